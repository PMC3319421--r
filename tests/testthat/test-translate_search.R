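# independent per-codon translator used as the oracle for the
# Biostrings-backed implementation
oracle_translate <- function(nt, off) {
  gc <- Biostrings::GENETIC_CODE
  n <- (nchar(nt) - off) %/% 3L
  if (n < 1L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, off + 3L * i - 2L, off + 3L * i)
    out[i] <- if (grepl("[^ACGT]", codon)) "X" else gc[[codon]]
  }
  paste(out, collapse = "")
}

revcomp <- function(nt)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))

test_that("six-frame translation follows the standard code", {
  pp <- six_frame_translate(c(r1 = "ATGTTTTAA"))
  expect_identical(pp$sequence[pp$frame == 1L], "MF*")
  expect_identical(pp$source_id, rep("r1", 6L))
  expect_sets_equal(pp$frame, c(1, 2, 3, -1, -2, -3))

  # frame lengths for a 10-base read: 3, 3, 2 on each strand
  pp10 <- six_frame_translate(c(r = "ACGTACGTAC"))
  expect_identical(nchar(pp10$sequence), rep(c(3L, 3L, 2L), 2L))

  # ambiguity codons translate to X
  ppn <- six_frame_translate(c(r = "ATGNNATTT"))
  expect_identical(ppn$sequence[ppn$frame == 1L], "MXF")

  expect_warning(six_frame_translate(c(tiny = "AC")), "shorter")
})

test_that("all six frames agree with a per-codon oracle", {
  withr::local_seed(101)
  for (rep in 1:20) {
    nt <- paste(sample(c("A", "C", "G", "T", "N"), sample(9:60, 1), TRUE,
                       prob = c(rep(0.24, 4), 0.04)), collapse = "")
    pp <- suppressWarnings(six_frame_translate(c(x = nt)))
    rc <- revcomp(nt)
    for (off in 0:2) {
      expect_identical(pp$sequence[pp$frame == off + 1L],
                       oracle_translate(nt, off))
      expect_identical(pp$sequence[pp$frame == -(off + 1L)],
                       oracle_translate(rc, off))
    }
    # reverse-complement identity
    prc <- six_frame_translate(c(x = rc))
    expect_identical(prc$sequence[prc$frame == 1L],
                     pp$sequence[pp$frame == -1L])
  }
})

test_that("SP hits are exact, unique per PP, and X never matches", {
  tab <- sp_table(SP14, "6.1.1.12")
  reads <- read_sequences(system.file("extdata",
                                      "example_reads_FYALPQAPQ.fasta",
                                      package = "spcount"))
  hits <- find_sp_hits(reads, tab)
  expect_identical(nrow(hits), 14L)
  # offset of the worked-example read 1, recomputed independently
  expect_identical(hits$offset[hits$source_id == "1"],
                   as.integer(regexpr(SP14, reads[["1"]], fixed = TRUE)) - 1L)
  # hits re-validate
  expect_true(all(substr(reads[hits$source_id], hits$offset + 1L,
                         hits$offset + 9L) == SP14))

  expect_identical(nrow(find_sp_hits(c(p = "AAAAALLLLL"), tab)), 0L)
  expect_identical(find_sp_hits(c(p = SP14), tab)$offset, 0L)

  # X in the PP blocks the match
  broken <- sub("L", "X", SP14)
  expect_identical(nrow(find_sp_hits(c(p = broken), tab)), 0L)

  # duplicate occurrence of a length >= 9 SP: first kept, warning raised
  twice <- paste0("AAA", SP14, "CCC", SP14)
  expect_warning(h2 <- find_sp_hits(c(p = twice), tab), "more than once")
  expect_identical(h2$offset, 3L)
})

test_that("putative proteins follow the stop/methionine rule", {
  # pp = AA*KMGG<SP>HH*TT with SP = SPWORDX-like 6-mer
  p <- extract_putative_protein("AA*KMGGSPWORDHH*TT", 7L, 6L)
  expect_identical(p$sequence, "MGGSPWORDHH")
  expect_identical(p$sp_offset, 3L)
  expect_false(p$trunc_start || p$trunc_end)

  # no left stop and no methionine: starts at the PP boundary, flagged
  p2 <- extract_putative_protein("GGSPWORDHH*TT", 2L, 6L)
  expect_identical(p2$sequence, "GGSPWORDHH")
  expect_true(p2$trunc_start)
  expect_false(p2$trunc_end)

  # no right stop: ends at the PP boundary, flagged
  p3 <- extract_putative_protein("AA*KMGGSPWORDHH", 7L, 6L)
  expect_identical(p3$sequence, "MGGSPWORDHH")
  expect_true(p3$trunc_end)

  # a stop inside the SP span contradicts the hit
  expect_error(extract_putative_protein("AASPW*RDHH", 2L, 6L),
               "cannot be genuine")
})

test_that("leading SP selection and grouping behave", {
  pps <- c(a = "AAAFYALPQAPQAAA", b = "CCCFYALPQAPQ", c = "FYALPQAPQGG",
           d = "TTTISRQLWWGHTT", e = "NAGISRQLWWGH")
  tab <- sp_table(c(SP14, "ISRQLWWGH", "DDNGLPTER"),
                  c("6.1.1.12", "6.1.1.12", "6.1.1.12"))
  hits <- find_sp_hits(pps, tab)
  lead <- select_leading_sp(hits, "6.1.1.12")
  expect_identical(lead$peptide, SP14)
  expect_identical(lead$n_pp, 3L)
  expect_error(select_leading_sp(hits, "9.9.9.9"), "no hits")

  groups <- group_by_sp(hits)
  expect_sets_equal(names(groups), c(SP14, "ISRQLWWGH"))
  expect_identical(nrow(groups[[SP14]]), 3L)
  expect_identical(nrow(groups[["ISRQLWWGH"]]), 2L)
  # anchors carry the hit offsets
  expect_identical(groups[[SP14]]$anchor[groups[[SP14]]$id == "a"], 3L)

  # tie on pp counts resolves lexicographically
  hits_tie <- find_sp_hits(pps[c("a", "d")], tab)
  expect_identical(select_leading_sp(hits_tie, "6.1.1.12")$peptide,
                   SP14)  # FYALPQAPQ < ISRQLWWGH
})

test_that("the 14 worked-example reads form one group of 14", {
  tab <- sp_table(SP14, "6.1.1.12")
  reads <- read_sequences(system.file("extdata",
                                      "example_reads_FYALPQAPQ.fasta",
                                      package = "spcount"))
  groups <- group_by_sp(find_sp_hits(reads, tab))
  expect_length(groups, 1L)
  expect_identical(nrow(groups[[SP14]]), 14L)

  expect_length(group_by_sp(find_sp_hits(c(x = "AAAA"), tab)), 0L)
})
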