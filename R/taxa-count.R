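#' Inconsistency graph of an anchored set
#'
#' Builds the graph whose vertices are the sequences and whose edges join
#' every inconsistent pair. The minimal number of source proteins able to
#' explain the set equals the chromatic number of this graph.
#'
#' @param seqs an [anchored_set()] sharing one SP.
#' @return an undirected [igraph][igraph::igraph-package] graph with
#'   vertex names taken from `seqs$id`.
#' @seealso [count_taxa_heuristic()], [chromatic_number_exact()]
#' @export
build_inconsistency_graph <- function(seqs) {
  stopifnot(inherits(seqs, "anchored_set"))
  n <- nrow(seqs)
  if (n == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  enc <- encode_anchored(seqs)
  C <- pairwise_conflicts(enc$M) > 0
  diag(C) <- FALSE
  dimnames(C) <- list(seqs$id, seqs$id)
  igraph::graph_from_adjacency_matrix(C, mode = "undirected")
}

#' Heuristic taxa count by string fusion
#'
#' Computes a lower bound on the number of taxa underlying a set of
#' SP-anchored sequences: the size of a minimal partition into mutually
#' consistent groups, each group merged into one fused string, such that
#' the fused strings are pairwise inconsistent.
#'
#' The procedure follows four steps: (1) sequences inconsistent with
#' every other sequence are removed and counted immediately; (2) the
#' remainder is split into blocks - connected components of the
#' consistency graph, since sequences in different blocks can never fuse;
#' (3) within each block, sequences are taken longest-first, substrings
#' are absorbed, and each sequence extends the consistent fused string
#' that yields the longest result (ties resolved toward the string holding
#' the earliest input sequence); (4) any two resulting strings that are
#' still consistent are merged, iterating to a fixpoint.
#'
#' Exactly identical (anchor-aligned) duplicates are collapsed before the
#' graph is built; their ids reappear in the `members` of the string that
#' absorbs them.
#'
#' @param seqs an [anchored_set()] sharing one SP.
#' @return an object of class `taxa_count`: a list with elements
#'   `count` (integer lower bound), `fused` (an `anchored_set` of the
#'   pairwise-inconsistent fused strings with a `members` list column),
#'   and `singles_first_pass` (number of sequences removed in step 1).
#' @examples
#' s <- anchored_set(c("a", "b"), c("KKSPWORDAA", "SPWORDAAGG"),
#'                   c(2L, 0L), sp = "SPWORD")
#' count_taxa_heuristic(s)$count
#' @export
count_taxa_heuristic <- function(seqs) {
  stopifnot(inherits(seqs, "anchored_set"))
  sp <- sp_of(seqs)
  if (nrow(seqs) == 0L) {
    fused <- anchored_set(character(0), character(0), integer(0), sp,
                          validate = FALSE)
    fused$members <- I(list())
    return(structure(list(count = 0L, fused = fused,
                          singles_first_pass = 0L, sp = sp),
                     class = "taxa_count"))
  }

  # collapse exact anchored duplicates
  key <- paste(seqs$anchor, seqs$sequence)
  first <- !duplicated(key)
  uniq <- seqs[first, , drop = FALSE]
  dup_members <- split(seqs$id, factor(key, levels = key[first]))

  n <- nrow(uniq)
  enc <- encode_anchored(uniq, with_coverage = TRUE)
  width <- ncol(enc$M)
  conflict <- pairwise_conflicts(enc$M) > 0
  diag(conflict) <- FALSE

  # step 1: first-pass singles - vertices adjacent to all others
  deg <- rowSums(conflict)
  singles <- which(deg == n - 1L)
  rest <- setdiff(seq_len(n), singles)

  # character frame for fusion bookkeeping (NA = uncovered)
  code2char <- character(max(.aa_codes) + 1L)
  code2char[.aa_codes + 1L] <- names(.aa_codes)
  code2char[1L] <- "X"
  CH <- matrix(NA_character_, n, width)
  CH[enc$COV] <- code2char[enc$M[enc$COV] + 1L]

  cov_len <- rowSums(enc$COV)

  new_string <- function(i) list(vec = CH[i, ], members = i)

  compatible <- function(str, i) {
    both <- !is.na(str$vec) & enc$COV[i, ]
    if (!any(both)) return(TRUE)
    a <- str$vec[both]; b <- CH[i, both]
    all(a == b | a == "X" | b == "X")
  }

  merge_into <- function(str, i) {
    covi <- enc$COV[i, ]
    take <- covi & (is.na(str$vec) | (str$vec == "X" & CH[i, ] != "X"))
    str$vec[take] <- CH[i, take]
    str$members <- c(str$members, i)
    str
  }

  # within one block, place reads one at a time into compatible fused
  # strings. Reads that conflict with many existing strings are placed
  # first (saturation order, exact on bipartite conflict structures);
  # ties fall back to the longest read, then the input order. Among the
  # compatible strings the one yielding the longest fusion wins, ties
  # toward the string holding the earliest read.
  block_greedy <- function(comp) {
    m <- length(comp)
    strings <- list()
    compat <- matrix(logical(0), nrow = m, ncol = 0L)
    unplaced <- rep(TRUE, m)
    while (any(unplaced)) {
      ui <- which(unplaced)
      sat <- if (ncol(compat))
        rowSums(!compat[ui, , drop = FALSE]) else rep(0L, length(ui))
      local <- ui[order(-sat, -cov_len[comp[ui]], comp[ui])][1L]
      i <- comp[local]
      cand <- if (ncol(compat)) which(compat[local, ]) else integer(0)
      if (!length(cand)) {
        strings[[length(strings) + 1L]] <- new_string(i)
        s <- length(strings)
      } else {
        gain <- vapply(cand, function(k) {
          sum(!is.na(strings[[k]]$vec) | enc$COV[i, ])
        }, numeric(1))
        anchor_id <- vapply(cand, function(k)
          min(strings[[k]]$members), numeric(1))
        s <- cand[order(-gain, anchor_id)][1L]
        strings[[s]] <- merge_into(strings[[s]], i)
      }
      unplaced[local] <- FALSE
      upd <- vapply(comp, function(k) compatible(strings[[s]], k),
                    logical(1))
      if (s > ncol(compat)) compat <- cbind(compat, upd)
      else compat[, s] <- upd
    }
    strings
  }

  strings <- list()
  for (comp in consistency_blocks(conflict, rest))
    strings <- c(strings, block_greedy(comp))
  strings <- c(lapply(singles, new_string), strings)

  # step 4: merge any strings that remain consistent, to a fixpoint
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > n + 1L) stop("fusion fixpoint did not converge")
    merged <- FALSE
    k <- length(strings)
    for (i in seq_len(max(k - 1L, 0L))) {
      for (j in (i + 1L):k) {
        if (strings_compatible(strings[[i]]$vec, strings[[j]]$vec)) {
          strings[[i]] <- merge_vecs(strings[[i]], strings[[j]])
          strings[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  fused <- strings_to_set(strings, dup_members, enc$gmin, sp)

  # postcondition: fused strings pairwise inconsistent
  if (nrow(fused) > 1L) {
    fc <- pairwise_conflicts(encode_anchored(fused)$M)
    diag(fc) <- 1
    if (any(fc == 0))
      stop("internal error: fused strings are not pairwise inconsistent")
  }

  structure(list(count = nrow(fused), fused = fused,
                 singles_first_pass = length(singles), sp = sp),
            class = "taxa_count")
}

# connected components of the consistency graph restricted to `rest`
consistency_blocks <- function(conflict, rest) {
  if (!length(rest)) return(list())
  m <- length(rest)
  adj <- !conflict[rest, rest, drop = FALSE]
  diag(adj) <- FALSE
  comp <- integer(m); cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(cur), function(k) rest[comp == k])
}

strings_compatible <- function(va, vb) {
  both <- !is.na(va) & !is.na(vb)
  if (!any(both)) return(TRUE)
  a <- va[both]; b <- vb[both]
  all(a == b | a == "X" | b == "X")
}

merge_vecs <- function(sa, sb) {
  take <- !is.na(sb$vec) & (is.na(sa$vec) | (sa$vec == "X" & sb$vec != "X"))
  sa$vec[take] <- sb$vec[take]
  sa$members <- c(sa$members, sb$members)
  sa
}

strings_to_set <- function(strings, dup_members, gmin, sp) {
  if (!length(strings)) {
    out <- anchored_set(character(0), character(0), integer(0), sp,
                        validate = FALSE)
    out$members <- I(list())
    return(out)
  }
  seqsv <- character(length(strings))
  anchors <- integer(length(strings))
  members <- vector("list", length(strings))
  for (k in seq_along(strings)) {
    vec <- strings[[k]]$vec
    cols <- which(!is.na(vec))
    if (any(diff(cols) != 1L))
      stop("internal error: fused string is not contiguous")
    seqsv[k] <- paste(vec[cols], collapse = "")
    # SP start (global 0) sits at column 1 - gmin
    anchors[k] <- (1L - gmin) - cols[1L]
    members[[k]] <- unlist(dup_members[sort(strings[[k]]$members)],
                           use.names = FALSE)
  }
  ord <- order(-nchar(seqsv), vapply(strings, function(s)
    min(s$members), numeric(1)))
  out <- anchored_set(paste0("F", seq_along(strings)), seqsv[ord],
                      anchors[ord], sp, validate = FALSE)
  out$members <- I(members[ord])
  attr(out, "sp") <- sp
  class(out) <- c("anchored_set", "data.frame")
  out
}

#' @export
print.taxa_count <- function(x, ...) {
  cat(sprintf(
    "taxa_count: lower bound %d (%d first-pass singles, %d fused strings) for SP '%s'\n",
    x$count, x$singles_first_pass, x$count - x$singles_first_pass, x$sp))
  invisible(x)
}

#' Exact chromatic number of an inconsistency graph
#'
#' Exact minimum proper colouring via backtracking with a clique lower
#' bound and a greedy upper bound, intended as an independent oracle for
#' [count_taxa_heuristic()] on small instances.
#'
#' @param g an undirected [igraph][igraph::igraph-package] graph (see
#'   [build_inconsistency_graph()]).
#' @param cap refuse instances with more vertices than this (the search is
#'   exponential); use the heuristic beyond it.
#' @return the chromatic number as an integer.
#' @export
chromatic_number_exact <- function(g, cap = 18L) {
  n <- igraph::vcount(g)
  if (n == 0L) return(0L)
  if (n > cap)
    stop("chromatic_number_exact: ", n, " vertices exceeds cap ", cap,
         "; use count_taxa_heuristic() for large instances")
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  if (!any(A)) return(1L)
  lb <- igraph::clique_num(g)

  ord <- order(-rowSums(A))
  A <- A[ord, ord, drop = FALSE]

  # greedy upper bound along the same order
  colors <- integer(n)
  for (v in seq_len(n)) {
    used <- colors[which(A[v, seq_len(v - 1L)])]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    colors[v] <- c0
  }
  best <- max(colors)
  if (best == lb) return(as.integer(lb))

  assign_col <- integer(n)
  recurse <- function(v, used) {
    if (used >= best) return(invisible(NULL))
    if (v > n) {
      best <<- used
      return(invisible(NULL))
    }
    forbidden <- unique(assign_col[which(A[v, seq_len(v - 1L)])])
    for (co in seq_len(min(used + 1L, best - 1L))) {
      if (co %in% forbidden) next
      assign_col[v] <<- co
      recurse(v + 1L, max(used, co))
      assign_col[v] <<- 0L
      if (best == lb) return(invisible(NULL))
    }
    invisible(NULL)
  }
  recurse(1L, 0L)
  as.integer(best)
}

#' Length cutoffs for non-leading sequence aggregation
#'
#' Default minimal putative-protein lengths (in residues) above which a
#' sequence lacking the leading SP is safely counted as an additional
#' gene rather than a fragment of an already-counted one: 700 for valyl-
#' (SYV, EC 6.1.1.9), 500 for glutaminyl- (SYQ, EC 6.1.1.18) and 450 for
#' threonyl-tRNA synthetase (SYT, EC 6.1.1.3).
#'
#' @param ec optional EC string; when given, the single cutoff for it.
#' @return named integer vector of cutoffs, or one integer.
#' @export
default_length_cutoff <- function(ec = NULL) {
  cutoffs <- c("6.1.1.9" = 700L, "6.1.1.18" = 500L, "6.1.1.3" = 450L)
  if (is.null(ec)) return(cutoffs)
  if (!ec %in% names(cutoffs))
    stop("no default length cutoff recorded for EC ", ec)
  cutoffs[[ec]]
}

#' Aggregate leading and non-leading counts into a lower bound
#'
#' Adds to the leading-SP taxa count the number of sufficiently long
#' sequences that carry only non-leading SPs of the same EC. The length
#' cutoff guards against double counting fragments of genes already
#' represented in the leading group.
#'
#' @param leading_count integer count from the leading-SP analysis.
#' @param nonleading putative proteins lacking the leading SP: a character
#'   vector of sequences, a numeric vector of lengths, or a data frame
#'   with a `sequence` or `length` column.
#' @param cutoff minimal length in residues (see
#'   [default_length_cutoff()]).
#' @param leading_sp optional: when supplied, sequences are checked not to
#'   contain this SP and an error is raised otherwise.
#' @return integer lower bound.
#' @export
aggregate_lower_bound <- function(leading_count, nonleading, cutoff,
                                  leading_sp = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop("cutoff must be a single non-negative number")
  lens <- if (is.numeric(nonleading)) {
    nonleading
  } else {
    seqs <- if (is.data.frame(nonleading)) {
      if (!is.null(nonleading$sequence)) nonleading$sequence
      else if (!is.null(nonleading$length)) NULL
      else stop("nonleading data frame needs a 'sequence' or 'length' column")
    } else as.character(nonleading)
    if (is.null(seqs)) {
      nonleading$length
    } else {
      if (!is.null(leading_sp) &&
          any(grepl(leading_sp, seqs, fixed = TRUE)))
        stop("some 'non-leading' sequences contain the leading SP")
      nchar(seqs)
    }
  }
  as.integer(leading_count + sum(lens >= cutoff))
}
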