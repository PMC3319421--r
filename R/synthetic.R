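#' Simulate taxa proteins sharing a planted SP
#'
#' Generates `K` source proteins that all carry the same SP exactly once,
#' at a shared offset, with independently drawn random flanks. The set is
#' rejection-sampled until (i) every pair differs at at least
#' `min_pair_distance` positions and (ii) for every pair, at least
#' `near_sp_fraction * min_pair_distance` of the differing positions lie
#' within one read length of the SP - the property that makes the taxa
#' distinguishable from SP-recruited short reads.
#'
#' @param K number of taxa, `>= 1`.
#' @param sp the planted SP word (default the worked-example marker
#'   `FYALPQAPQ`), or a one-row `sp_table` subset.
#' @param protein_length protein length in residues,
#'   `> nchar(sp)`.
#' @param min_pair_distance minimal pairwise anchored Hamming distance.
#' @param near_sp_fraction fraction of `min_pair_distance` required
#'   within the near-SP window.
#' @param read_length read length defining the near-SP window.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap.
#' @return a list of class `sp_truth`: `proteins` (an [anchored_set()]
#'   with ids `T1..TK`), `sp`, `anchor`, `distances` (pairwise anchored
#'   Hamming matrix), and the generating `params`.
#' @export
simulate_taxa_proteins <- function(K, sp = "FYALPQAPQ",
                                   protein_length = 120L,
                                   min_pair_distance = 10L,
                                   near_sp_fraction = 0.3,
                                   read_length = 24L,
                                   seed = NULL, max_tries = 100L) {
  if (is.data.frame(sp)) sp <- sp$peptide[1L]
  spl <- nchar(sp)
  stopifnot(K >= 1L, protein_length > spl)
  flank <- protein_length - spl
  if (K > 1L && min_pair_distance > flank)
    stop("infeasible: min_pair_distance exceeds the ", flank,
         " non-SP positions")
  if (!is.null(seed)) withr::local_seed(seed)
  anchor <- (protein_length - spl) %/% 2L
  near_lo <- pmax(anchor - read_length, 0L)
  near_hi <- pmin(anchor + spl + read_length, protein_length)
  need_near <- ceiling(near_sp_fraction * min_pair_distance)

  for (try in seq_len(max_tries)) {
    prot <- vapply(seq_len(K), function(i) {
      left <- paste(sample_aa(anchor), collapse = "")
      right <- paste(sample_aa(protein_length - spl - anchor),
                     collapse = "")
      paste0(left, sp, right)
    }, character(1))
    # the SP must occur exactly once
    if (any(vapply(gregexpr(sp, prot, fixed = TRUE), length,
                   integer(1)) != 1L)) next
    chars <- do.call(rbind, strsplit(prot, ""))
    ok <- TRUE
    D <- matrix(0L, K, K)
    if (K > 1L) {
      near <- seq(near_lo + 1L, near_hi)
      for (i in seq_len(K - 1L)) {
        for (j in (i + 1L):K) {
          diffp <- which(chars[i, ] != chars[j, ])
          D[i, j] <- D[j, i] <- length(diffp)
          if (length(diffp) < min_pair_distance ||
              sum(diffp %in% near) < need_near) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) {
      proteins <- anchored_set(paste0("T", seq_len(K)), prot,
                               rep(anchor, K), sp)
      dimnames(D) <- list(proteins$id, proteins$id)
      return(structure(list(proteins = proteins, sp = sp, anchor = anchor,
                            distances = D,
                            params = list(K = K,
                                          protein_length = protein_length,
                                          min_pair_distance = min_pair_distance,
                                          near_sp_fraction = near_sp_fraction,
                                          read_length = read_length,
                                          seed = seed)),
                       class = "sp_truth"))
    }
  }
  stop("simulate_taxa_proteins: constraints not met after ", max_tries,
       " attempts; relax min_pair_distance or near_sp_fraction")
}

#' @export
print.sp_truth <- function(x, ...) {
  cat(sprintf("sp_truth: %d taxa proteins of %d aa, SP '%s' at offset %d\n",
              nrow(x$proteins), x$params$protein_length, x$sp, x$anchor))
  invisible(x)
}

#' Simulate short reads from simulated taxa
#'
#' Draws `coverage` reads per taxon with uniformly random start
#' positions. With `require_sp` the starts are restricted so that every
#' read contains the full SP (emulating SP-based recruitment). With
#' `nucleotide` the amino-acid reads are reverse-translated through
#' uniformly chosen synonymous codons and emitted on a random strand, so
#' that six-frame translation recovers each amino-acid read in exactly
#' one frame.
#'
#' @param truth an `sp_truth` from [simulate_taxa_proteins()].
#' @param read_length read length in residues; must be `>= nchar(sp)`
#'   when `require_sp`.
#' @param coverage reads per taxon.
#' @param require_sp restrict reads to those covering the SP.
#' @param nucleotide emit nucleotide reads instead of amino-acid reads.
#' @param error_rate per-residue (amino-acid mode) or per-base
#'   (nucleotide mode) substitution probability applied after read
#'   extraction; in amino-acid mode, reads whose SP is destroyed are
#'   dropped as in [inject_errors()].
#' @param seed integer seed.
#' @return a list of class `sp_reads`: `seqs` (an [anchored_set()] in
#'   amino-acid mode, a named character vector of nucleotide reads
#'   otherwise), `meta` (read id, taxon, 0-based span, strand) and
#'   `nucleotide` flag.
#' @export
simulate_reads <- function(truth, read_length = 24L, coverage = 10L,
                           require_sp = TRUE, nucleotide = FALSE,
                           error_rate = 0, seed = NULL) {
  stopifnot(inherits(truth, "sp_truth"))
  spl <- nchar(truth$sp)
  plen <- truth$params$protein_length
  if (require_sp && read_length < spl)
    stop("read_length must be >= the SP length when require_sp = TRUE")
  if (read_length > plen) stop("read_length exceeds the protein length")
  if (!is.null(seed)) withr::local_seed(seed)
  anchor <- truth$anchor
  lo <- if (require_sp) max(0L, anchor - (read_length - spl)) else 0L
  hi <- if (require_sp) min(anchor, plen - read_length) else
    plen - read_length
  K <- nrow(truth$proteins)
  meta <- data.frame(id = character(K * coverage),
                     taxon = character(K * coverage),
                     start = integer(K * coverage),
                     end = integer(K * coverage),
                     strand = NA_character_, stringsAsFactors = FALSE)
  seqs <- character(K * coverage)
  k <- 0L
  for (t in seq_len(K)) {
    prot <- truth$proteins$sequence[t]
    for (r in seq_len(coverage)) {
      k <- k + 1L
      start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      seqs[k] <- substr(prot, start + 1L, start + read_length)
      meta$id[k] <- sprintf("R%d_%d", t, r)
      meta$taxon[k] <- truth$proteins$id[t]
      meta$start[k] <- start
      meta$end[k] <- start + read_length
    }
  }
  if (nucleotide) {
    nt <- vapply(seqs, reverse_translate, character(1), USE.NAMES = FALSE)
    if (error_rate > 0) nt <- vapply(nt, mutate_nt, character(1),
                                     p = error_rate, USE.NAMES = FALSE)
    rc <- sample(c(TRUE, FALSE), length(nt), replace = TRUE)
    nt[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(nt[rc])))
    meta$strand <- ifelse(rc, "-", "+")
    out_seqs <- stats::setNames(nt, meta$id)
  } else {
    aset <- anchored_set(meta$id, seqs, anchor - meta$start, truth$sp)
    if (error_rate > 0) {
      aset <- inject_errors(aset, error_rate)
      meta <- meta[meta$id %in% aset$id, , drop = FALSE]
    }
    out_seqs <- aset
  }
  structure(list(seqs = out_seqs, meta = meta, nucleotide = nucleotide,
                 params = list(read_length = read_length,
                               coverage = coverage,
                               require_sp = require_sp,
                               error_rate = error_rate, seed = seed)),
            class = "sp_reads")
}

# uniform synonymous codon choice under the standard genetic code
reverse_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  chars <- split1(aa)
  codons <- vapply(chars, function(ch) {
    if (ch == "*") ch_codons <- names(gc)[gc == "*"]
    else if (ch == "X") return("NNN")
    else ch_codons <- names(gc)[gc == ch]
    if (!length(ch_codons)) stop("cannot reverse-translate symbol ", ch)
    if (length(ch_codons) == 1L) ch_codons else sample(ch_codons, 1L)
  }, character(1))
  paste(codons, collapse = "")
}

mutate_nt <- function(seq, p) {
  chars <- split1(seq)
  hit <- chars %in% c("A", "C", "G", "T") &
    (stats::runif(length(chars)) < p)
  if (any(hit)) {
    idx <- which(hit)
    nts <- c("A", "C", "G", "T")
    old <- match(chars[idx], nts)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- nts[((old - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Simulate an annotated toy genome
#'
#' Concatenates reverse-translated genes (each closed by a stop codon)
#' with random intergenic spacers, producing a nucleotide genome together
#' with its genic/intergenic [region_annotation()] - a fixture for
#' [evaluate_specificity()].
#'
#' @param genes data frame with columns `protein` and `ec` (or a list of
#'   `c(protein, ec)` pairs); may be empty.
#' @param spacer_length intergenic spacer length in nucleotides,
#'   `>= 0`.
#' @param seed integer seed.
#' @return list of class `sp_genome`: `genome` (named character of length
#'   1), `annotation`, `genic_length`, `intergenic_length`.
#' @export
simulate_annotated_genome <- function(genes, spacer_length = 100L,
                                      seed = NULL) {
  stopifnot(spacer_length >= 0L)
  if (!is.data.frame(genes))
    genes <- do.call(rbind, lapply(genes, function(g)
      data.frame(protein = g[[1L]], ec = g[[2L]],
                 stringsAsFactors = FALSE)))
  if (is.null(genes))
    genes <- data.frame(protein = character(0), ec = character(0))
  if (!is.null(seed)) withr::local_seed(seed)
  spacer <- function() paste(sample(c("A", "C", "G", "T"), spacer_length,
                                    replace = TRUE), collapse = "")
  parts <- character(0)
  starts <- ends <- integer(0)
  pos <- 0L
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  if (spacer_length > 0L) add(spacer())
  for (g in seq_len(nrow(genes))) {
    nt <- paste0(reverse_translate(genes$protein[g]), "TAA")
    starts <- c(starts, pos); ends <- c(ends, pos + nchar(nt))
    add(nt)
    if (spacer_length > 0L) add(spacer())
  }
  genome <- stats::setNames(paste(parts, collapse = ""), "synthetic_genome")
  glen <- nchar(genome)[[1L]]
  gaps <- interval_complement(starts, ends, glen)
  ann <- region_annotation(
    seqid = "synthetic_genome",
    start = c(starts, gaps$start), end = c(ends, gaps$end),
    class = c(rep("genic", length(starts)),
              rep("intergenic", length(gaps$start))),
    ec = c(genes$ec, rep(NA_character_, length(gaps$start))))
  structure(list(genome = genome, annotation = ann,
                 genic_length = sum(ends - starts),
                 intergenic_length = glen - sum(ends - starts)),
            class = "sp_genome")
}
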