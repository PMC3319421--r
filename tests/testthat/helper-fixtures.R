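# Shared fixtures and generators. Everything is built in code or read
# from the small plain-text files under inst/extdata.

SP14 <- "FYALPQAPQ"

# the 14-read worked example (river-sediment short reads sharing the
# aspartate-tRNA-synthetase marker FYALPQAPQ)
table14_set <- function() {
  path <- system.file("extdata", "example_reads_FYALPQAPQ.fasta",
                      package = "spcount")
  seqs <- read_sequences(path)
  anchored_set(names(seqs), unname(seqs),
               as.integer(regexpr(SP14, seqs, fixed = TRUE)) - 1L, SP14)
}

# the four-sequence toy instance: a-s-b, a-s-b-c, d-s-b, s-b-e around a
# shared SP word s
toy_abcd <- function() {
  s <- "SSSSSSSSS"
  anchored_set(c("A", "B", "C", "D"),
               c(paste0("A", s, "B"), paste0("A", s, "BC"),
                 paste0("D", s, "B"), paste0(s, "BE")),
               c(1L, 1L, 1L, 0L), s)
}

AA20 <- spcount:::AA20

rand_sp <- function(len = 9L) paste(sample(AA20, len, TRUE), collapse = "")

# stated-world random instance: reads drawn from K simulated taxa
# proteins (iid divergent flanks, pairwise distance >= 10 with near-SP
# distinguishing positions); n <= 15 anchored sequences
rand_world_instance <- function(max_n = 15L) {
  K <- sample(1:5, 1L)
  rl <- sample(15:24, 1L)
  truth <- simulate_taxa_proteins(K, protein_length = 60L,
                                  min_pair_distance = 10L,
                                  read_length = rl,
                                  seed = sample.int(2^30, 1L))
  n <- sample(2:max_n, 1L)
  reads <- simulate_reads(truth, rl, ceiling(n / K),
                          seed = sample.int(2^30, 1L))
  reads$seqs[sample(nrow(reads$seqs), min(n, nrow(reads$seqs))), ]
}

# adversarial instance family: near-duplicate variants of one backbone
# protein (0-4 substitutions each), producing dense, path-like
# consistency structures
rand_backbone_instance <- function(max_n = 15L) {
  sp <- rand_sp()
  plen <- 40L
  anchor <- 15L
  repeat {
    backbone <- paste0(paste(sample(AA20, anchor), collapse = ""), sp,
                       paste(sample(AA20, plen - anchor - 9L),
                             collapse = ""))
    if (length(gregexpr(sp, backbone, fixed = TRUE)[[1L]]) == 1L) break
  }
  K <- sample(1:5, 1L)
  prots <- vapply(seq_len(K), function(i) {
    ch <- strsplit(backbone, "")[[1L]]
    pos <- sample(setdiff(seq_len(plen), (anchor + 1L):(anchor + 9L)),
                  sample(0:4, 1L))
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1))
  n <- sample(2:max_n, 1L)
  rl <- sample(12:25, 1L)
  seqs <- character(n); anchors <- integer(n)
  for (i in seq_len(n)) {
    t <- sample(K, 1L)
    s <- sample(max(0L, anchor - (rl - 9L)):min(anchor, plen - rl), 1L)
    seqs[i] <- substr(prots[t], s + 1L, s + rl)
    anchors[i] <- anchor - s
  }
  if (!all(substr(seqs, anchors + 1L, anchors + 9L) == sp))
    return(NULL)  # a substitution recreated the SP elsewhere; rare
  anchored_set(paste0("r", seq_len(n)), seqs, anchors, sp)
}

expect_sets_equal <- function(object, expected) {
  expect_setequal(as.character(object), as.character(expected))
}
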