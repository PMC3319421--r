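test_that("probability of inequality matches exhaustive enumeration", {
  # identical proteins: every window matches
  r <- inequality_probability(list(c("MKVLYAANDE", "MKVLYAANDE")), 4L)
  expect_identical(r$P_ine, 0)

  # disjoint residue alphabets: no window can match
  r2 <- inequality_probability(list(c("AAAAA", "CCCCCCC")), 3L)
  expect_identical(r2$P_ine, 1)

  # windows {AB, BC, CD} of ABCD against ZABCZ: only CD misses
  r3 <- inequality_probability(list(c("ABCD", "ZABCZ")), 2L)
  expect_identical(r3$N_dif, 1L)
  expect_identical(r3$Sigma, 3L)
  expect_equal(r3$P_ine, 1 / 3)

  # pairs re-ordered by length internally; short pairs skipped
  r4 <- inequality_probability(list(c("ZABCZ", "ABCD")), 2L)
  expect_equal(r4$P_ine, 1 / 3)
  expect_warning(
    r5 <- inequality_probability(list(c("AB", "AAAA"), c("ABCD", "ZABCZ")),
                                 3L), "skipped")
  expect_identical(r5$n_pairs, 1L)
})

test_that("no-match indicators are monotone in W at fixed window start", {
  withr::local_seed(12)
  for (rep in 1:10) {
    shorter <- paste(sample(AA20, 15, TRUE), collapse = "")
    longer <- paste(sample(AA20, 30, TRUE), collapse = "")
    # plant a shared region so that some windows match
    substr(longer, 8, 14) <- substr(shorter, 4, 10)
    for (start in 1:6) {
      prev <- FALSE
      for (W in 1:8) {
        win <- substr(shorter, start, start + W - 1L)
        nomatch <- !grepl(win, longer, fixed = TRUE)
        expect_true(nomatch >= prev)  # once lost, never matches again
        prev <- nomatch
      }
    }
  }
})

test_that("inequality curves decrease towards longer matches never", {
  pairs <- list(c("MKVLYAANDEFGHIK", "MKVLYAANDEWWWWWFGHIK"))
  cur <- inequality_curve(pairs, c(3, 5, 8))
  expect_identical(names(cur), c("W", "N_dif", "Sigma", "P_ine"))
  expect_true(all(diff(cur$P_ine) >= 0))  # larger windows only harder
})

test_that("rank-discordant pairs pick same-higher different-lower", {
  tax <- data.frame(family = c("F1", "F1", "F1", "F2"),
                    genus = c("G1", "G1", "G2", "G3"))
  prs <- rank_discordant_pairs(tax, "family", "genus")
  got <- apply(prs, 1L, paste, collapse = "-")
  expect_sets_equal(got, c("1-3", "2-3"))
})

test_that("error injection is calibrated, anchored and reproducible", {
  truth <- simulate_taxa_proteins(3L, protein_length = 400L, seed = 88)
  seqs <- truth$proteins

  expect_identical(inject_errors(seqs, 0)$sequence, seqs$sequence)

  all_mut <- suppressMessages(inject_errors(seqs, 1))
  # any survivor (SP untouched is impossible at p = 1) would be a bug
  expect_identical(nrow(all_mut), 0L)
  expect_identical(attr(all_mut, "n_sp_mutated"), 3L)

  # with drop = FALSE the set is kept whole and every residue differs
  kept <- inject_errors(seqs, 1, seed = 2, drop = FALSE)
  expect_identical(nrow(kept), 3L)
  expect_true(all(mapply(function(a, b)
    !any(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]),
    kept$sequence, seqs$sequence)))

  # binomial calibration: ~1000 substitutions expected on 1e5 residues
  big <- anchored_set("big",
                      paste0(SP14, paste(rep("A", 1e5 - 9L), collapse = "")),
                      0L, SP14)
  mut <- inject_errors(big, 0.01, seed = 4)
  if (nrow(mut)) {
    nm <- sum(strsplit(mut$sequence, "")[[1]] !=
                strsplit(big$sequence, "")[[1]])
    expect_lt(abs(nm - 0.01 * 1e5), 4 * sqrt(1e5 * 0.01 * 0.99))
  }

  a <- suppressMessages(inject_errors(seqs, 0.05, seed = 9))
  b <- suppressMessages(inject_errors(seqs, 0.05, seed = 9))
  expect_identical(a, b)
})

test_that("the error-shift table reduces to the clean curve at p = 0", {
  withr::local_seed(3)
  inst <- rand_world_instance()
  es <- error_shift_check(inst, 0, d_max = 4L)
  clean <- count_curve(count_taxa_heuristic(inst)$fused, 4L)$count
  expect_identical(es$clean, clean)
  expect_identical(es$mutated, clean)
  expect_identical(es$shift[-4L], clean[-1L] - clean[-4L])
  expect_true(is.na(es$shift[4L]))

  single <- anchored_set("only", paste0("KK", SP14, "GG"), 2L, SP14)
  es1 <- error_shift_check(single, 0.01, d_max = 2L, seed = 1)
  expect_identical(es1$clean, rep(1L, 2L))
})

test_that("specificity evaluation classifies planted hits", {
  tab <- sp_table(SP14, "6.1.1.12")
  prot <- function(seed) {
    simulate_taxa_proteins(1L, protein_length = 60L, seed = seed
                           )$proteins$sequence
  }
  genes <- data.frame(protein = c(prot(1), prot(2), prot(3), prot(4)),
                      ec = c("6.1.1.12", "6.1.1.12", "6.1.1.12",
                             "1.1.1.1"))
  gen <- simulate_annotated_genome(genes, spacer_length = 90L, seed = 10)
  res <- evaluate_specificity(gen$genome, gen$annotation, tab)
  row <- res[res$L == 9L, ]
  expect_identical(row$TP, 3L)
  expect_identical(row$FP, 1L)
  expect_equal(row$error, 0.25)
  expect_identical(row$intergenic, 0L)
  expect_identical(row$EFP, 0L)
  expect_identical(attr(res, "genic_length"), gen$genic_length)
  expect_identical(attr(res, "unclassified"), 0L)

  # equal genic and intergenic lengths: EFP equals the raw count
  expect_identical(as.integer(round(5L * 1000 / 1000)), 5L)
  efp <- evaluate_specificity(
    gen$genome,
    region_annotation("synthetic_genome",
                      c(0L, 500L), c(500L, nchar(gen$genome)),
                      c("genic", "intergenic"), c("6.1.1.12", NA)),
    tab)
  expect_identical(efp$EFP,
                   as.integer(round(efp$intergenic * 500 /
                                      (nchar(gen$genome) - 500))))
})

test_that("random intergenic sequence yields (almost) no L >= 9 hits", {
  withr::local_seed(77)
  tab <- sp_table(c(SP14, "ISRQLWWGH", "TRFPPEPNGYLH"),
                  c("6.1.1.12", "6.1.1.9", "6.1.1.18"))
  genome <- stats::setNames(
    paste(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = ""), "g")
  ann <- region_annotation("g", 0L, 1e5L, "intergenic")
  res <- evaluate_specificity(genome, ann, tab)
  expect_identical(sum(res$TP) + sum(res$FP), 0L)
  expect_lte(sum(res$intergenic), 1L)  # 20^-9 per position; ~0 expected
})

test_that("match profiles find planted matches and are monotone", {
  truth <- simulate_taxa_proteins(4L, seed = 21)
  reads <- simulate_reads(truth, 24L, 3L, seed = 22)
  ref <- stats::setNames(truth$proteins$sequence, truth$proteins$id)

  verb <- match_to_reference(reads$seqs, ref, k_max = 3L)
  expect_identical(verb$fraction[verb$k == 0L], 1)

  # one planted mismatch outside the SP moves everything to k = 1
  qs <- reads$seqs
  qs$sequence <- vapply(seq_len(nrow(qs)), function(i) {
    s <- qs$sequence[i]
    pos <- if (qs$anchor[i] > 0L) 1L else nchar(s)  # outside the SP span
    old <- substr(s, pos, pos)
    paste0(substr(s, 1L, pos - 1L),
           setdiff(AA20, old)[1L],
           substr(s, pos + 1L, nchar(s)))
  }, character(1))
  one <- match_to_reference(qs, ref, k_max = 3L)
  expect_identical(one$fraction[one$k == 0L], 0)
  expect_identical(one$fraction[one$k == 1L], 1)
  expect_true(all(diff(one$fraction) >= 0))

  # reference sharing only the SP: mismatches everywhere outside it
  alien <- paste0(strrep("W", 30), SP14, strrep("W", 30))
  far <- match_to_reference(reads$seqs, c(ref1 = alien), k_max = 3L)
  expect_identical(far$fraction[far$k <= 3L], rep(0, 4L))

  expect_error(match_to_reference(reads$seqs, character(0)), "empty")

  # free-offset mode finds verbatim reads too
  free <- match_to_reference(reads$seqs$sequence, ref, k_max = 1L)
  expect_identical(free$fraction[free$k == 0L], 1)
})
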