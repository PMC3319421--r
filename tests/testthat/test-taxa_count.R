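test_that("consistency matches the worked-example relations", {
  a <- table14_set()
  r <- function(i) a[a$id == as.character(i), ]
  expect_true(are_consistent(r(1), r(8)))
  expect_false(are_consistent(r(3), r(8)))   # R vs K downstream of the SP
  expect_true(are_consistent(r(1), r(1)))    # reflexivity

  other <- anchored_set("z", "AAADDNGLPTERAAA", 3L, "DDNGLPTER")
  expect_error(are_consistent(r(1), other), "different SP")
})

test_that("consistency is symmetric and X acts as a wildcard", {
  withr::local_seed(7)
  for (rep in 1:10) {
    inst <- rand_world_instance(8L)
    for (i in seq_len(nrow(inst) - 1L))
      for (j in (i + 1L):nrow(inst))
        expect_identical(are_consistent(inst[i, ], inst[j, ]),
                         are_consistent(inst[j, ], inst[i, ]))
  }
  s <- anchored_set(c("a", "b"),
                    c("KXSPWIRDAA", "KYSPWIRDAB"), c(2L, 2L), "SPWIRD")
  # X at position 2 matches Y, but A vs B downstream still conflicts
  expect_false(are_consistent(s[1, ], s[2, ]))
  s2 <- anchored_set(c("a", "b"),
                     c("KXSPWIRDAA", "KYSPWIRDAA"), c(2L, 2L), "SPWIRD")
  expect_true(are_consistent(s2[1, ], s2[2, ]))
})

test_that("the toy instance builds the expected graph and counts", {
  toy <- toy_abcd()
  g <- build_inconsistency_graph(toy)
  edges <- apply(igraph::as_edgelist(g), 1L,
                 function(e) paste(sort(e), collapse = "-"))
  expect_sets_equal(edges, c("A-C", "B-C", "B-D"))
  expect_identical(chromatic_number_exact(g), 2L)

  res <- count_taxa_heuristic(toy)
  expect_identical(res$count, 2L)
  expect_sets_equal(unlist(res$fused$members), c("A", "B", "C", "D"))
  # the two fused strings realise a-s-b-c and d-s-b-e
  expect_sets_equal(res$fused$sequence,
                    c("ASSSSSSSSSBC", "DSSSSSSSSSBE"))
})

test_that("an all-identical set is edgeless and counts one taxon", {
  s <- anchored_set(paste0("r", 1:5), rep("AASPWIRDGG", 5L), rep(2L, 5L),
                    "SPWIRD")
  g <- build_inconsistency_graph(s)
  expect_equal(igraph::ecount(g), 0)
  expect_identical(chromatic_number_exact(g), 1L)
  res <- count_taxa_heuristic(s)
  expect_identical(res$count, 1L)
  expect_length(res$fused$members[[1L]], 5L)
})

test_that("fusion reproduces the worked-example strings", {
  a <- table14_set()
  f <- fuse(a[a$id %in% c("1", "6", "8"), ])
  expect_identical(
    f$sequence,
    "ILTSSSPEGARDFLVPSRLNPGKFYALPQAPQQFKQLIMVSGFDKYFQIA")
  expect_true(substr(f$sequence, f$anchor + 1L, f$anchor + 9L) == SP14)

  # reads 10 and 13 are substrings of read 3: fusing changes nothing
  f2 <- fuse(a[a$id %in% c("3", "10", "13"), ])
  expect_identical(f2$sequence, a$sequence[a$id == "3"])

  # single sequence fuses to itself
  f3 <- fuse(a[a$id == "5", ])
  expect_identical(f3$sequence, a$sequence[a$id == "5"])

  # inconsistent members are rejected
  expect_error(fuse(a[a$id %in% c("3", "8"), ]), "disagree")

  # a concrete residue overrides the X wildcard
  s <- anchored_set(c("a", "b"), c("KXSPWIRDA", "KYSPWIRD"),
                    c(2L, 2L), "SPWIRD")
  expect_identical(fuse(s)$sequence, "KYSPWIRDA")
})

test_that("the heuristic solves the worked example: 8 + 2 = 10", {
  res <- count_taxa_heuristic(table14_set())
  expect_identical(res$count, 10L)
  expect_identical(res$singles_first_pass, 8L)
  expect_identical(nrow(res$fused), 10L)
  # every read appears in exactly one fused string
  members <- unlist(res$fused$members)
  expect_sets_equal(members, as.character(1:14))
  expect_identical(anyDuplicated(members), 0L)
})

test_that("degenerate heuristic inputs", {
  sp <- "SPWIRD"
  empty <- anchored_set(character(0), character(0), integer(0), sp)
  expect_identical(count_taxa_heuristic(empty)$count, 0L)
  one <- anchored_set("x", "AASPWIRDCC", 2L, sp)
  expect_identical(count_taxa_heuristic(one)$count, 1L)
})

test_that("heuristic output is a valid partition with invariant bounds", {
  withr::local_seed(42)
  for (rep in 1:25) {
    inst <- rand_world_instance()
    res <- count_taxa_heuristic(inst)
    expect_identical(res$count, nrow(res$fused))
    members <- unlist(res$fused$members)
    expect_sets_equal(members, inst$id)
    expect_identical(anyDuplicated(members), 0L)
    # fused strings pairwise inconsistent
    if (nrow(res$fused) > 1L)
      for (i in seq_len(nrow(res$fused) - 1L))
        for (j in (i + 1L):nrow(res$fused))
          expect_false(are_consistent(res$fused[i, ], res$fused[j, ]))
    # partition size bounded below by the largest clique
    g <- build_inconsistency_graph(inst)
    expect_gte(res$count, igraph::clique_num(g))
  }
})

test_that("heuristic equals the exact oracle on adversarial instances", {
  withr::local_seed(31415)
  done <- 0L
  while (done < 30L) {
    inst <- rand_backbone_instance()
    if (is.null(inst)) next
    done <- done + 1L
    expect_identical(count_taxa_heuristic(inst)$count,
                     chromatic_number_exact(build_inconsistency_graph(inst)))
  }
})

test_that("exact chromatic number handles canonical graphs", {
  path4 <- igraph::make_graph(~ A - C, C - B, B - D)
  expect_identical(chromatic_number_exact(path4), 2L)
  expect_identical(chromatic_number_exact(igraph::make_empty_graph(3,
    directed = FALSE)), 1L)
  expect_identical(chromatic_number_exact(igraph::make_full_graph(8)), 8L)
  expect_identical(chromatic_number_exact(igraph::make_ring(5)), 3L)
  expect_error(chromatic_number_exact(igraph::make_full_graph(19)),
               "cap")
})

test_that("aggregation adds only sufficiently long non-leading proteins", {
  expect_identical(aggregate_lower_bound(10L, c(710, 699, 800), 700L), 12L)
  expect_identical(aggregate_lower_bound(10L, numeric(0), 700L), 10L)
  expect_identical(aggregate_lower_bound(3L, c("AAAA", "AAAAAA"), 5L), 4L)
  expect_error(aggregate_lower_bound(10L, c(1, 2), -1), "non-negative")
  expect_error(
    aggregate_lower_bound(1L, paste0("AA", SP14, "AA"), 2L,
                          leading_sp = SP14),
    "contain the leading SP")

  cutoffs <- default_length_cutoff()
  expect_identical(cutoffs[["6.1.1.9"]], 700L)
  expect_identical(cutoffs[["6.1.1.18"]], 500L)
  expect_identical(cutoffs[["6.1.1.3"]], 450L)
  expect_identical(default_length_cutoff("6.1.1.3"), 450L)
  expect_error(default_length_cutoff("1.2.3.4"), "no default")
})
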