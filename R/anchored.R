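#' Anchored sequence sets
#'
#' An `anchored_set` holds amino-acid strings that all carry the same
#' specific peptide (SP), each annotated with the 0-based offset (`anchor`)
#' of the single SP occurrence. The anchor fixes a common coordinate
#' system: position `i` (0-based) of a sequence with anchor `a` sits at
#' global coordinate `i - a`, so that the SP always spans global
#' coordinates `[0, nchar(sp))`. All pairwise comparisons in the package
#' (consistency, fusion, anchored Hamming distance) operate in this frame.
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence amino-acid strings (may contain `X` wildcards and `*`).
#' @param anchor 0-based offsets of the SP occurrence in each sequence.
#' @param sp the shared SP word.
#' @param validate check that `sp` occurs at each anchor (`X` in the
#'   sequence is accepted as matching any SP residue).
#' @return a data frame of class `anchored_set` with columns `id`,
#'   `sequence`, `anchor` and attribute `sp`.
#' @examples
#' anchored_set(c("a", "b"), c("MKFYALPQAPQW", "FYALPQAPQWW"),
#'              c(2L, 0L), sp = "FYALPQAPQ")
#' @export
anchored_set <- function(id, sequence, anchor, sp, validate = TRUE) {
  id <- as.character(id)
  sequence <- normalize_aa(as.character(sequence))
  anchor <- as.integer(anchor)
  stopifnot(length(id) == length(sequence), length(id) == length(anchor))
  if (anyDuplicated(id)) stop("anchored_set: ids must be unique")
  sp <- normalize_aa(sp)
  spl <- nchar(sp)
  if (length(id)) {
    if (any(anchor < 0L) || any(anchor + spl > nchar(sequence)))
      stop("anchored_set: anchor out of range for sequence length")
    if (validate) {
      word <- substr(sequence, anchor + 1L, anchor + spl)
      ok <- sp_word_matches(word, sp)
      if (!all(ok))
        stop("anchored_set: SP '", sp, "' not found at anchor for id(s): ",
             paste(id[!ok], collapse = ", "))
    }
  }
  out <- data.frame(id = id, sequence = sequence, anchor = anchor,
                    stringsAsFactors = FALSE)
  attr(out, "sp") <- sp
  class(out) <- c("anchored_set", "data.frame")
  out
}

# exact match of the anchored word against the SP, treating 'X' in the
# observed word as a wildcard
sp_word_matches <- function(word, sp) {
  if (!length(word)) return(logical(0))
  spc <- split1(sp)
  vapply(word, function(w) {
    wc <- split1(w)
    all(wc == spc | wc == "X")
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
`[.anchored_set` <- function(x, ...) {
  out <- NextMethod()
  if (inherits(out, "data.frame")) {
    attr(out, "sp") <- attr(x, "sp")
    class(out) <- class(x)
  }
  out
}

#' @export
print.anchored_set <- function(x, ...) {
  cat(sprintf("anchored_set: %d sequence(s) sharing SP '%s'\n",
              nrow(x), attr(x, "sp")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

sp_of <- function(x) {
  sp <- attr(x, "sp")
  if (is.null(sp)) stop("object carries no SP attribute")
  sp
}

check_same_sp <- function(a, b) {
  spa <- if (!is.null(a$sp)) a$sp else sp_of(a)
  spb <- if (!is.null(b$sp)) b$sp else sp_of(b)
  if (!identical(spa, spb))
    stop("sequences anchored at different SP words ('", spa, "' vs '",
         spb, "')")
  spa
}

# --- anchored coordinate matrices -----------------------------------------

# Encode an anchored set as an integer matrix over the global coordinate
# frame. Columns run over [gmin, gmax) where gmin = min(-anchor).
# Entries: 0 for uncovered positions *and* 'X' wildcards (both are inert
# in comparisons), residue codes otherwise. A parallel logical coverage
# matrix distinguishes the two where it matters (fusion).
encode_anchored <- function(x, with_coverage = FALSE) {
  n <- nrow(x)
  lens <- nchar(x$sequence)
  g0 <- -x$anchor
  gmin <- min(g0)
  width <- max(g0 + lens) - gmin
  M <- matrix(0L, n, width)
  COV <- if (with_coverage) matrix(FALSE, n, width) else NULL
  for (i in seq_len(n)) {
    cols <- (g0[i] - gmin) + seq_len(lens[i])
    M[i, cols] <- aa_encode(split1(x$sequence[i]))
    if (with_coverage) COV[i, cols] <- TRUE
  }
  list(M = M, COV = COV, gmin = gmin, ids = x$id)
}

# Pairwise counts of positions at which two rows hold distinct concrete
# residues (wildcards and uncovered positions never conflict). This single
# kernel yields both the inconsistency relation (count > 0) and the
# anchored Hamming distance (the count itself).
pairwise_conflicts <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  concrete <- M > 0L
  for (r in sort(unique(M[concrete]))) {
    A <- M == r
    D <- D + tcrossprod(A, concrete & !A)
  }
  D
}

# --- pairwise operations ---------------------------------------------------

as_anchored_row <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot(nrow(x) == 1L)
    out <- list(sequence = x$sequence, anchor = x$anchor,
                sp = attr(x, "sp"))
  } else {
    out <- list(sequence = x$sequence, anchor = as.integer(x$anchor),
                sp = x$sp)
  }
  out
}

overlap_chars <- function(a, b) {
  ca <- split1(a$sequence); cb <- split1(b$sequence)
  # global coordinates covered by each (0-based)
  ga <- seq_along(ca) - 1L - a$anchor
  gb <- seq_along(cb) - 1L - b$anchor
  lo <- max(ga[1L], gb[1L]); hi <- min(ga[length(ga)], gb[length(gb)])
  if (hi < lo) return(NULL)  # cannot happen when both cover the SP
  g <- lo:hi
  list(a = ca[g + 1L + a$anchor], b = cb[g + 1L + b$anchor])
}

#' Consistency of two anchored sequences
#'
#' Two sequences sharing an SP are *consistent* when they agree at every
#' position of their anchored overlap; the `X` wildcard agrees with
#' anything. Inconsistent sequences cannot stem from the same protein and
#' therefore mark different taxa.
#'
#' @param a,b single anchored sequences: one-row subsets of an
#'   [anchored_set()] or lists with elements `sequence`, `anchor`, `sp`.
#' @return `TRUE` or `FALSE`.
#' @export
are_consistent <- function(a, b) {
  a <- as_anchored_row(a); b <- as_anchored_row(b)
  check_same_sp(a, b)
  ov <- overlap_chars(a, b)
  all(ov$a == ov$b | ov$a == "X" | ov$b == "X")
}

#' Anchored Hamming distance
#'
#' Number of positions of the anchored overlap at which two sequences hold
#' differing residues. Positions where either side is `X` (or not covered)
#' are excluded. The overlap always contains the SP span, which
#' contributes zero by construction.
#'
#' @inheritParams are_consistent
#' @return non-negative integer distance.
#' @export
anchored_hamming <- function(a, b) {
  a <- as_anchored_row(a); b <- as_anchored_row(b)
  check_same_sp(a, b)
  ov <- overlap_chars(a, b)
  sum(ov$a != ov$b & ov$a != "X" & ov$b != "X")
}

#' Fuse mutually consistent anchored sequences
#'
#' Merges a set of pairwise consistent sequences into one longer string
#' over the union of their anchored coordinates (contiguous, since every
#' member covers the SP span). Each position takes the unique residue
#' agreed on by the covering members; `X` is overwritten by any concrete
#' residue.
#'
#' @param seqs an [anchored_set()] whose members are pairwise consistent.
#' @return a one-row `anchored_set` with an additional list column
#'   `members` holding the absorbed sequence ids.
#' @export
fuse <- function(seqs) {
  stopifnot(inherits(seqs, "anchored_set"), nrow(seqs) >= 1L)
  sp <- sp_of(seqs)
  enc <- encode_anchored(seqs, with_coverage = TRUE)
  res <- fuse_encoded(enc$M, enc$COV)
  if (!is.null(res$conflict))
    stop("fuse: members disagree at anchored position ",
         res$conflict + enc$gmin, " (relative to SP start)")
  # global coordinate 0 sits at matrix column (-gmin + 1); the fused
  # string starts at column res$start, so its SP offset is the difference
  out <- anchored_set(id = paste(seqs$id, collapse = "U"),
                      sequence = res$sequence,
                      anchor = (-enc$gmin + 1L) - res$start,
                      sp = sp, validate = FALSE)
  out$members <- I(list(seqs$id))
  attr(out, "sp") <- sp
  class(out) <- c("anchored_set", "data.frame")
  out
}

# column-wise merge on encoded matrices; returns character sequence, the
# first covered column, or the offending column on conflict
fuse_encoded <- function(M, COV) {
  covered <- colSums(COV) > 0L
  cols <- which(covered)
  if (any(diff(cols) != 1L))
    stop("fuse: union of anchored spans is not contiguous")
  code2char <- character(max(.aa_codes) + 1L)
  code2char[.aa_codes + 1L] <- names(.aa_codes)
  code2char[1L] <- "X"
  seq_chars <- character(length(cols))
  for (k in seq_along(cols)) {
    col <- cols[k]
    vals <- M[COV[, col], col]
    conc <- unique(vals[vals > 0L])
    if (length(conc) > 1L)
      return(list(conflict = col))
    seq_chars[k] <- if (length(conc)) code2char[conc + 1L] else "X"
  }
  list(sequence = paste(seq_chars, collapse = ""), start = cols[1L],
       conflict = NULL)
}
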