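#' Anchored Hamming distance matrix of fused strings
#'
#' Computes all pairwise anchored Hamming distances between the members of
#' an anchored set (typically the fused strings returned by
#' [count_taxa_heuristic()]). Rows/columns are ordered by increasing
#' string length (ties by id), so that in the upper triangle the left
#' index of a pair always refers to the shorter string.
#'
#' @param strings an [anchored_set()] sharing one SP.
#' @return an object of class `sp_distmat`: a list with the integer
#'   distance `matrix`, the parallel `overlap` matrix (number of jointly
#'   covered positions), the ordered `ids`, and `sp_only`, a logical
#'   matrix flagging pairs whose overlap is just the SP span and which
#'   therefore carry no discriminative signal.
#' @export
distance_matrix <- function(strings) {
  stopifnot(inherits(strings, "anchored_set"))
  sp <- sp_of(strings)
  ord <- order(nchar(strings$sequence), strings$id)
  x <- strings[ord, , drop = FALSE]
  attr(x, "sp") <- sp
  class(x) <- c("anchored_set", "data.frame")
  enc <- encode_anchored(x, with_coverage = TRUE)
  D <- pairwise_conflicts(enc$M)
  O <- tcrossprod(enc$COV)
  dimnames(D) <- dimnames(O) <- list(x$id, x$id)
  structure(list(matrix = D, overlap = O, ids = x$id,
                 sp_only = O <= nchar(sp), sp = sp),
            class = "sp_distmat")
}

#' @export
print.sp_distmat <- function(x, ...) {
  cat(sprintf("sp_distmat: %d strings, SP '%s'\n", length(x$ids), x$sp))
  invisible(x)
}

as_distmat <- function(m) {
  if (inherits(m, "sp_distmat")) return(m)
  if (inherits(m, "anchored_set")) return(distance_matrix(m))
  if (is.matrix(m))
    return(structure(list(matrix = m, overlap = NULL,
                          ids = rownames(m) %||% as.character(seq_len(nrow(m))),
                          sp_only = NULL, sp = NA_character_),
                     class = "sp_distmat"))
  stop("expected an sp_distmat, anchored_set or square matrix")
}

# one round of the pair-removal procedure: list pairs (i < j, i.e. shorter
# vs longer) at distance <= d among the surviving indices, drop the
# smaller column of unique indices (ties toward the left/shorter column),
# and repeat on the residual pair list until no pair remains.
remove_close_pairs <- function(D, surv, d) {
  repeat {
    if (length(surv) < 2L) break
    sub <- D[surv, surv, drop = FALSE]
    hit <- which(upper.tri(sub) & sub <= d, arr.ind = TRUE)
    if (!nrow(hit)) break
    left <- unique(hit[, 1L])
    right <- unique(hit[, 2L])
    minimal <- if (length(left) <= length(right)) left else right
    surv <- surv[-minimal]
  }
  surv
}

#' Count strings separated by more than a minimal distance
#'
#' Removes members of pairs whose anchored Hamming distance is at most
#' `d`, following the index-pair procedure: collect all pairs (shorter
#' index left, longer right) at distance `<= d`, take the unique indices
#' of each column, remove the smaller of the two sets (ties toward the
#' left), and iterate on the residual pairs until none remain. The
#' survivors are certified to be pairwise more than `d` apart.
#'
#' @param m an `sp_distmat` (or an anchored set / plain matrix).
#' @param d minimal distance threshold, `d >= 0`; pairs at distance
#'   `<= d` are collapsed.
#' @return integer count of surviving strings, with the surviving ids in
#'   attribute `survivors`.
#' @export
count_at_min_distance <- function(m, d) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0)
  m <- as_distmat(m)
  n <- length(m$ids)
  surv <- remove_close_pairs(m$matrix, seq_len(n), d)
  # certify against the matrix rather than trusting the procedure
  if (length(surv) > 1L) {
    sub <- m$matrix[surv, surv, drop = FALSE]
    if (any(sub[upper.tri(sub)] <= d))
      stop("internal error: surviving pair at distance <= ", d)
  }
  structure(length(surv), survivors = m$ids[surv])
}

#' Taxa count as a function of minimal distance
#'
#' Produces the count-versus-distance curve: the point at distance `d`
#' counts the strings that remain once all pairs closer than `d` (anchored
#' Hamming distance `<= d - 1`) have been collapsed, so the point at
#' `d = 1` is the plain count of mutually inconsistent strings and larger
#' `d` progressively merges strains and close species. Removal is applied
#' cumulatively with increasing `d`, which makes the curve non-increasing
#' by construction.
#'
#' @param strings an [anchored_set()] of fused strings (or an
#'   `sp_distmat`).
#' @param d_max largest minimal distance to evaluate, `>= 1`.
#' @return a data frame of class `count_curve` with columns `d` and
#'   `count`.
#' @export
count_curve <- function(strings, d_max) {
  stopifnot(is.numeric(d_max), length(d_max) == 1L, d_max >= 1)
  m <- as_distmat(strings)
  n <- length(m$ids)
  surv <- seq_len(n)
  counts <- integer(d_max)
  for (d in seq_len(d_max)) {
    surv <- remove_close_pairs(m$matrix, surv, d - 1L)
    counts[d] <- length(surv)
  }
  structure(data.frame(d = seq_len(d_max), count = counts),
            class = c("count_curve", "data.frame"))
}

#' Exact minimal-distance count for small instances
#'
#' The pair-removal procedure of [count_at_min_distance()] is a heuristic
#' for the maximum set of strings that are pairwise more than `d` apart
#' (a maximum independent set in the "close-pair" graph). This exact
#' version quantifies the gap on small instances.
#'
#' @inheritParams count_at_min_distance
#' @param cap refuse instances with more strings than this.
#' @return integer: the maximum number of strings pairwise more than `d`
#'   apart.
#' @export
count_at_min_distance_exact <- function(m, d, cap = 25L) {
  m <- as_distmat(m)
  n <- length(m$ids)
  if (n > cap)
    stop("exact independent-set count capped at ", cap, " strings")
  if (n == 0L) return(0L)
  close <- m$matrix <= d
  diag(close) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(close, mode = "undirected")
  as.integer(igraph::independence_number(g))
}

#' Subsampled taxa counts at increasing depth
#'
#' Draws `trials` random subsamples of `S` sequences without replacement,
#' runs the full counting pipeline on each ([count_taxa_heuristic()]
#' followed by [count_curve()]), and summarises the counts per minimal
#' distance by their mean and standard error of the mean.
#'
#' @param seqs an [anchored_set()] (population of size `N_p`).
#' @param S sample size, `1 <= S <= nrow(seqs)`.
#' @param trials number of random trials (default 20).
#' @param d_max largest minimal distance for the curves.
#' @param seed integer seed making the draw reproducible.
#' @return a data frame of class `subsample_counts` with columns `d`,
#'   `mean`, `sem`, and attributes `S`, `N_p`, `trials`, `seed`.
#' @export
subsample_counts <- function(seqs, S, trials = 20L, d_max = 10L,
                             seed = NULL) {
  stopifnot(inherits(seqs, "anchored_set"))
  N_p <- nrow(seqs)
  if (S < 1L || S > N_p)
    stop("sample size S must satisfy 1 <= S <= ", N_p)
  sp <- sp_of(seqs)
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- matrix(0L, trials, d_max)
  for (t in seq_len(trials)) {
    take <- sort(sample.int(N_p, S))
    sub <- seqs[take, , drop = FALSE]
    attr(sub, "sp") <- sp
    class(sub) <- c("anchored_set", "data.frame")
    res <- count_taxa_heuristic(sub)
    counts[t, ] <- count_curve(res$fused, d_max)$count
  }
  mean_c <- colMeans(counts)
  sem <- apply(counts, 2L, stats::sd) / sqrt(trials)
  structure(data.frame(d = seq_len(d_max), mean = mean_c, sem = sem),
            class = c("subsample_counts", "data.frame"),
            S = S, N_p = N_p, trials = trials, seed = seed)
}
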