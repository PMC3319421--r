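#' Probability of inequality at a window size
#'
#' For each supplied pair of proteins, slides every window of `W` residues
#' along the shorter protein and asks whether it occurs anywhere in the
#' longer protein as an exact substring. Aggregating over all windows and
#' pairs yields `P_ine = N_dif / Sigma`, the probability that a window of
#' length `W` distinguishes the two proteins - the taxonomic acuity
#' achievable with reads of that length.
#'
#' @param pairs a list of length-2 character vectors `(shorter, longer)`
#'   or a two-column data frame/matrix of protein sequences; pairs are
#'   re-ordered by length internally.
#' @param W window size in residues, `>= 1`. Pairs whose shorter protein
#'   is below `W` are skipped with a warning.
#' @return a list of class `inequality_result` with `W`, `N_dif`,
#'   `Sigma`, `P_ine`, and `n_pairs` (pairs actually used).
#' @export
inequality_probability <- function(pairs, W) {
  stopifnot(is.numeric(W), length(W) == 1L, W >= 1)
  pairs <- as_pair_list(pairs)
  n_dif <- 0L; sigma <- 0L; used <- 0L
  for (p in pairs) {
    lens <- nchar(p)
    shorter <- p[which.min(lens)]; longer <- p[which.max(lens)]
    ns <- nchar(shorter)
    if (ns < W) {
      warning("pair skipped: shorter protein (", ns,
              " aa) is below window size ", W)
      next
    }
    used <- used + 1L
    win <- substring(shorter, 1:(ns - W + 1L), W:ns)
    nl <- nchar(longer)
    lmers <- substring(longer, 1:(nl - W + 1L), W:nl)
    n_dif <- n_dif + sum(!(win %in% lmers))
    sigma <- sigma + length(win)
  }
  structure(list(W = W, N_dif = n_dif, Sigma = sigma,
                 P_ine = if (sigma) n_dif / sigma else NA_real_,
                 n_pairs = used),
            class = "inequality_result")
}

as_pair_list <- function(pairs) {
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    stopifnot(ncol(pairs) == 2L)
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(i) as.character(unlist(pairs[i, ])))
  }
  stopifnot(is.list(pairs), all(lengths(pairs) == 2L))
  pairs
}

#' @export
print.inequality_result <- function(x, ...) {
  cat(sprintf("P_ine = %d/%d = %.4f at W = %d (%d pairs)\n",
              x$N_dif, x$Sigma, x$P_ine, x$W, x$n_pairs))
  invisible(x)
}

#' Probability-of-inequality curve over window sizes
#'
#' @inheritParams inequality_probability
#' @param W_values vector of window sizes.
#' @return data frame with columns `W`, `N_dif`, `Sigma`, `P_ine`.
#' @export
inequality_curve <- function(pairs, W_values) {
  do.call(rbind, lapply(W_values, function(w) {
    r <- inequality_probability(pairs, w)
    data.frame(W = r$W, N_dif = r$N_dif, Sigma = r$Sigma, P_ine = r$P_ine)
  }))
}

#' Pairs of proteins discordant at a taxonomy rank
#'
#' Selects all pairs of proteins that share the same label at a higher
#' rank but differ at a lower rank - the pairs over which
#' [inequality_probability()] gauges the acuity of that rank boundary.
#'
#' @param taxonomy data frame of rank labels (one row per protein).
#' @param higher,lower column names of the two consecutive ranks.
#' @return two-column matrix of row indices (one row per pair).
#' @export
rank_discordant_pairs <- function(taxonomy, higher, lower) {
  stopifnot(all(c(higher, lower) %in% names(taxonomy)))
  idx <- seq_len(nrow(taxonomy))
  out <- list()
  for (grp in split(idx, taxonomy[[higher]])) {
    if (length(grp) < 2L) next
    cmb <- utils::combn(grp, 2L)
    diffr <- taxonomy[[lower]][cmb[1L, ]] != taxonomy[[lower]][cmb[2L, ]]
    if (any(diffr)) out[[length(out) + 1L]] <- t(cmb[, diffr, drop = FALSE])
  }
  if (!length(out)) return(matrix(integer(0), 0L, 2L))
  do.call(rbind, out)
}

#' Inject per-residue substitution errors
#'
#' Emulates sequencing/translation errors: each residue is independently
#' substituted with probability `p` by a uniformly chosen different
#' residue. Substitution-only (no indels), so anchors stay valid where
#' the SP survives; sequences whose SP span is mutated are dropped with a
#' message, mirroring the real pipeline in which recruitment requires an
#' exact SP hit (the expected drop fraction is `1 - (1-p)^L`).
#'
#' @param seqs an [anchored_set()].
#' @param p per-residue substitution probability in `[0, 1]`.
#' @param seed integer seed for reproducibility.
#' @param drop drop sequences whose SP span was mutated (the default,
#'   emulating recruitment). With `drop = FALSE` they are retained
#'   unchanged-in-place, as when errors are injected into an already
#'   recruited set without re-running the SP search.
#' @return the mutated `anchored_set`; attribute `n_sp_mutated` records
#'   how many sequences lost their SP (dropped or retained).
#' @export
inject_errors <- function(seqs, p, seed = NULL, drop = TRUE) {
  stopifnot(inherits(seqs, "anchored_set"), p >= 0, p <= 1)
  sp <- sp_of(seqs)
  if (!is.null(seed)) withr::local_seed(seed)
  mut <- vapply(seqs$sequence, mutate_aa, character(1), p = p,
                USE.NAMES = FALSE)
  word <- substr(mut, seqs$anchor + 1L, seqs$anchor + nchar(sp))
  intact <- word == sp
  keep <- if (drop) intact else rep(TRUE, length(intact))
  if (drop && any(!intact))
    message("inject_errors: dropped ", sum(!intact),
            " sequence(s) whose SP span was mutated")
  out <- anchored_set(seqs$id[keep], mut[keep], seqs$anchor[keep], sp,
                      validate = drop)
  attr(out, "n_sp_mutated") <- sum(!intact)
  out
}

#' Error-shift calibration diagnostic
#'
#' Compares the count-versus-distance curve of a clean anchored set with
#' the curve obtained after injecting substitution errors at rate `p`.
#' Errors inflate the count at minimal distance 1; the diagnostic
#' tabulates `count_mutated(d + 1) - count_clean(d)`, which should be
#' small when counting at `d + 1` absorbs the error-induced splits.
#'
#' @param original an [anchored_set()] of error-free sequences.
#' @param p per-residue substitution probability.
#' @param d_max largest minimal distance evaluated.
#' @param seed integer seed for the error injection.
#' @param drop passed to [inject_errors()]. The default `FALSE` mirrors
#'   the calibration construction, in which errors are injected into an
#'   already recruited set without re-running the SP search.
#' @return data frame of class `error_shift` with columns `d`, `clean`,
#'   `mutated` and `shift` (`mutated[d + 1] - clean[d]`, `NA` at
#'   `d = d_max`).
#' @export
error_shift_check <- function(original, p, d_max = 5L, seed = NULL,
                              drop = FALSE) {
  stopifnot(inherits(original, "anchored_set"))
  clean <- count_curve(count_taxa_heuristic(original)$fused, d_max)
  mutated <- inject_errors(original, p, seed = seed, drop = drop)
  mut <- count_curve(count_taxa_heuristic(mutated)$fused, d_max)
  shift <- c(mut$count[-1L] - clean$count[-d_max], NA_integer_)
  structure(data.frame(d = clean$d, clean = clean$count,
                       mutated = mut$count, shift = shift),
            class = c("error_shift", "data.frame"))
}

#' SP specificity on an annotated genome
#'
#' Searches SP hits on the six-frame translation of a genome, maps each
#' hit back to nucleotide coordinates, and classifies it by the region it
#' falls in: genic hits are true positives when the overlapping gene
#' carries the SP's EC and false positives otherwise, while intergenic
#' hits form a negative set from which the number of *expected* false
#' positives in genic regions (EFP) is extrapolated by the genic to
#' intergenic length ratio.
#'
#' @param genome a single nucleotide sequence (named character of length
#'   1, or a plain string).
#' @param annotation a [region_annotation()]; if it contains no
#'   intergenic intervals they are taken as the complement of the genic
#'   ones over the genome.
#' @param table an `sp_table`, typically loaded with `min_length = 7`.
#' @return a data frame of class `specificity_table`, one row per SP
#'   length `L`: `L`, `TP`, `FP`, `error` (`FP / (FP + TP)`),
#'   `intergenic`, `EFP`; attributes `genic_length`,
#'   `intergenic_length` and `unclassified`.
#' @export
evaluate_specificity <- function(genome, annotation, table) {
  stopifnot(inherits(table, "sp_table"),
            inherits(annotation, "region_annotation"))
  if (length(genome) != 1L) stop("expected a single genome sequence")
  gid <- names(genome) %||% unique(annotation$seqid)[1L]
  glen <- nchar(genome)[[1L]]

  genic <- annotation[annotation$class == "genic" &
                        annotation$seqid == gid, , drop = FALSE]
  inter <- annotation[annotation$class == "intergenic" &
                        annotation$seqid == gid, , drop = FALSE]
  if (!nrow(inter)) {
    gaps <- interval_complement(genic$start, genic$end, glen)
    inter <- data.frame(seqid = gid, start = gaps$start, end = gaps$end,
                        class = "intergenic", ec = NA_character_)
  }
  genic_len <- sum(genic$end - genic$start)
  inter_len <- sum(inter$end - inter$start)

  pps <- six_frame_translate(stats::setNames(as.character(genome), gid))
  hits <- find_sp_hits(pps, table, all_occurrences = TRUE)
  Ls <- sort(unique(table$length))
  tp <- fp <- ig <- stats::setNames(integer(length(Ls)), Ls)
  unclassified <- 0L

  for (k in seq_len(nrow(hits))) {
    L <- nchar(hits$sp[k])
    span <- hit_to_genomic(hits$frame[k], hits$offset[k], L, glen)
    gi <- which(genic$start < span[2L] & genic$end > span[1L])
    if (length(gi)) {
      if (any(!is.na(genic$ec[gi]) & genic$ec[gi] == hits$ec[k]))
        tp[as.character(L)] <- tp[as.character(L)] + 1L
      else
        fp[as.character(L)] <- fp[as.character(L)] + 1L
    } else if (any(inter$start < span[2L] & inter$end > span[1L])) {
      ig[as.character(L)] <- ig[as.character(L)] + 1L
    } else {
      unclassified <- unclassified + 1L
      warning("SP hit at ", span[1L], "-", span[2L],
              " not covered by the annotation")
    }
  }

  efp <- if (inter_len > 0) as.integer(round(ig * genic_len / inter_len))
         else rep(NA_integer_, length(Ls))
  out <- data.frame(L = Ls, TP = unname(tp), FP = unname(fp),
                    error = ifelse(tp + fp > 0, fp / (tp + fp), NA_real_),
                    intergenic = unname(ig), EFP = efp)
  structure(out, class = c("specificity_table", "data.frame"),
            genic_length = genic_len, intergenic_length = inter_len,
            unclassified = unclassified)
}

# 0-based half-open genomic span of an amino-acid hit in a given frame
hit_to_genomic <- function(frame, offset, n_res, genome_length) {
  off <- abs(frame) - 1L
  lo <- off + 3L * offset
  hi <- off + 3L * (offset + n_res)
  if (frame > 0L) c(lo, hi) else c(genome_length - hi, genome_length - lo)
}

interval_complement <- function(start, end, total) {
  if (!length(start))
    return(list(start = if (total > 0L) 0L else integer(0),
                end = if (total > 0L) total else integer(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  gs <- c(0L, end); ge <- c(start, total)
  keep <- gs < ge
  list(start = gs[keep], end = ge[keep])
}

#' Match anchored queries against a reference protein set
#'
#' For each query read, finds the best-matching reference protein and
#' tabulates, for every mismatch allowance `k`, the fraction of queries
#' whose best match has at most `k` mismatches. By default the alignment
#' is anchored: queries are aligned at every occurrence of the shared SP
#' in a reference protein, and query positions falling outside the
#' reference count as mismatches. With `free_offset = TRUE` every full
#' embedding of the query in the reference is tried instead.
#'
#' @param queries an [anchored_set()] (anchored mode) or character vector
#'   (free-offset mode).
#' @param reference named character vector of reference proteins.
#' @param k_max largest mismatch allowance tabulated.
#' @param free_offset ignore anchors and scan all embeddings.
#' @return a data frame of class `match_profile` with columns `k` and
#'   `fraction` (non-decreasing in `k`); attribute `best` holds the
#'   per-query best mismatch counts.
#' @export
match_to_reference <- function(queries, reference, k_max = 10L,
                               free_offset = FALSE) {
  if (!length(reference)) stop("empty reference protein set")
  reference <- normalize_aa(as.character(reference))
  if (!inherits(queries, "anchored_set")) free_offset <- TRUE
  qseq <- if (inherits(queries, "anchored_set")) queries$sequence
          else normalize_aa(as.character(queries))
  n <- length(qseq)
  best <- rep(Inf, n)
  if (free_offset) {
    for (i in seq_len(n)) {
      qc <- split1(qseq[i]); ql <- length(qc)
      for (ref in reference) {
        rc <- split1(ref)
        if (length(rc) < ql) next
        for (o in 0:(length(rc) - ql)) {
          mm <- sum(qc != rc[o + seq_len(ql)] & qc != "X")
          if (mm < best[i]) best[i] <- mm
          if (best[i] == 0) break
        }
        if (best[i] == 0) break
      }
    }
  } else {
    sp <- sp_of(queries)
    ref_anchors <- lapply(reference, function(r) {
      p <- gregexpr(sp, r, fixed = TRUE)[[1L]]
      if (p[1L] == -1L) integer(0) else as.integer(p) - 1L
    })
    for (i in seq_len(n)) {
      qc <- split1(qseq[i]); ql <- length(qc)
      qa <- queries$anchor[i]
      for (r in seq_along(reference)) {
        anchors <- ref_anchors[[r]]
        if (!length(anchors)) next
        rc <- split1(reference[r])
        for (ra in anchors) {
          ridx <- seq_len(ql) - 1L - qa + ra + 1L
          inside <- ridx >= 1L & ridx <= length(rc)
          mm <- sum(!inside) +
            sum(qc[inside] != rc[ridx[inside]] & qc[inside] != "X")
          if (mm < best[i]) best[i] <- mm
        }
        if (best[i] == 0) break
      }
    }
  }
  ks <- 0:k_max
  frac <- vapply(ks, function(k) mean(best <= k), numeric(1))
  structure(data.frame(k = ks, fraction = frac),
            class = c("match_profile", "data.frame"), best = best)
}
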