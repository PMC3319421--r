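#' Six-frame translation of nucleotide sequences
#'
#' Translates each read in all six reading frames (offsets 0..2 on the
#' forward strand, frames `+1..+3`; the same offsets on the reverse
#' complement, frames `-1..-3`) under the standard genetic code. Stops are
#' rendered `*` and any codon containing an ambiguity letter renders `X`.
#' The resulting amino-acid strings are the putative peptides (PPs) on
#' which SP hits are searched.
#'
#' @param reads named character vector of nucleotide sequences (alphabet
#'   `A C G T N`; other IUPAC letters are tolerated and translate to `X`).
#' @return a data frame of class `pp_set` with columns `source_id`,
#'   `frame` (integer in `+1..+3`, `-1..-3`) and `sequence`. Reads
#'   shorter than one codon yield empty frames with a warning.
#' @examples
#' six_frame_translate(c(r1 = "ATGTTTTAA"))
#' @export
six_frame_translate <- function(reads) {
  ids <- names(reads) %||% paste0("seq", seq_along(reads))
  reads <- toupper(as.character(reads))
  if (any(nchar(reads) < 3L))
    warning("read(s) shorter than one codon produce empty frames: ",
            paste(ids[nchar(reads) < 3L], collapse = ", "))
  out <- vector("list", 6L * length(reads))
  k <- 0L
  for (i in seq_along(reads)) {
    fwd <- Biostrings::DNAString(reads[i])
    rev <- Biostrings::reverseComplement(fwd)
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) fwd else rev
      for (off in 0:2) {
        k <- k + 1L
        out[[k]] <- data.frame(
          source_id = ids[i], frame = strand * (off + 1L),
          sequence = translate_frame(s, off), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("pp_set", "data.frame")
  out
}

translate_frame <- function(dna, off) {
  n <- length(dna)
  naa <- (n - off) %/% 3L
  if (naa < 1L) return("")
  sub <- Biostrings::subseq(dna, off + 1L, off + 3L * naa)
  as.character(Biostrings::translate(sub, no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Search SP hits on putative peptides
#'
#' Exact substring search of every SP of a table on a collection of
#' putative peptides (or plain amino-acid sequences). `X` never matches an
#' SP residue, preserving the specificity of exact peptide matching. An SP
#' of length `>= 9` is expected to occur at most once per PP; additional
#' occurrences are dropped with a warning and only the first is recorded.
#'
#' @param pps a `pp_set` from [six_frame_translate()], or a named
#'   character vector of amino-acid sequences (each treated as its own PP
#'   with frame `NA`).
#' @param table an `sp_table` (see [read_sp_table()], [sp_table()]).
#' @param all_occurrences record every occurrence of an SP on a PP
#'   instead of the first only. Reads and single-gene contigs carry one
#'   occurrence; whole-genome translations (see
#'   [evaluate_specificity()]) legitimately carry many.
#' @return a data frame of class `sp_hits` with columns `source_id`,
#'   `frame`, `pp` (row index into `pps`), `sp`, `ec`, `offset` (0-based
#'   start of the SP in the PP).
#' @export
find_sp_hits <- function(pps, table, all_occurrences = FALSE) {
  stopifnot(inherits(table, "sp_table"))
  if (!inherits(pps, "data.frame")) {
    seqs <- normalize_aa(as.character(pps))
    pps <- data.frame(source_id = names(pps) %||%
                        paste0("seq", seq_along(pps)),
                      frame = NA_integer_, sequence = seqs,
                      stringsAsFactors = FALSE)
    class(pps) <- c("pp_set", "data.frame")
  }
  hits <- vector("list", nrow(table))
  for (s in seq_len(nrow(table))) {
    pep <- table$peptide[s]
    pos <- gregexpr(pep, pps$sequence, fixed = TRUE)
    if (all_occurrences) {
      rows <- lapply(which(vapply(pos, `[[`, integer(1), 1L) > 0L),
                     function(i) data.frame(
                       source_id = pps$source_id[i], frame = pps$frame[i],
                       pp = i, sp = pep, ec = table$ec[s],
                       offset = as.integer(pos[[i]]) - 1L,
                       stringsAsFactors = FALSE))
      if (length(rows)) hits[[s]] <- do.call(rbind, rows)
    } else {
      first <- vapply(pos, `[[`, integer(1), 1L)
      extra <- vapply(pos, length, integer(1)) > 1L
      hit <- which(first > 0L)
      if (any(extra) && table$length[s] >= 9L)
        warning("SP ", pep, " occurs more than once on PP(s) ",
                paste(pps$source_id[extra], collapse = ", "),
                "; keeping the first occurrence")
      if (length(hit))
        hits[[s]] <- data.frame(source_id = pps$source_id[hit],
                                frame = pps$frame[hit], pp = hit,
                                sp = pep, ec = table$ec[s],
                                offset = first[hit] - 1L,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(source_id = character(0), frame = integer(0),
                      pp = integer(0), sp = character(0), ec = character(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sp_hits", "data.frame")
  attr(out, "pps") <- pps
  out
}

#' Extract the putative protein around an SP hit
#'
#' Applies the gene-section rule: the protein starts at the first
#' methionine following the closest stop signal to the left of the SP and
#' ends just before the first stop signal downstream of the SP. Either
#' boundary falling off the PP (no stop, or no methionine after the stop)
#' is flagged as a truncation, so that downstream length filters can treat
#' such fragments conservatively.
#'
#' @param pp a PP amino-acid string (may contain `*`).
#' @param offset 0-based SP start within `pp`.
#' @param sp_length SP length in residues.
#' @return a list with `sequence` (no internal `*`), `sp_offset` (0-based
#'   SP start within the extracted protein), `start`/`end` (0-based
#'   half-open span in PP coordinates), and flags `trunc_start`
#'   (sequence does not begin at a methionine) and `trunc_end` (no
#'   downstream stop observed).
#' @export
extract_putative_protein <- function(pp, offset, sp_length) {
  chars <- split1(pp)
  n <- length(chars)
  sp_from <- offset + 1L; sp_to <- offset + sp_length
  stopifnot(sp_from >= 1L, sp_to <= n)
  if (any(chars[sp_from:sp_to] == "*"))
    stop("stop codon inside the SP span: the hit cannot be genuine")
  stops <- which(chars == "*")
  ls <- stops[stops < sp_from]
  ls <- if (length(ls)) max(ls) else 0L
  m <- which(chars == "M")
  m <- m[m > ls & m <= sp_from]
  if (length(m)) {
    start <- min(m); trunc_start <- FALSE
  } else {
    start <- ls + 1L; trunc_start <- TRUE
  }
  rs <- stops[stops > sp_to]
  if (length(rs)) {
    end <- min(rs) - 1L; trunc_end <- FALSE
  } else {
    end <- n; trunc_end <- TRUE
  }
  list(sequence = paste(chars[start:end], collapse = ""),
       sp_offset = sp_from - start,
       start = start - 1L, end = end,
       trunc_start = trunc_start, trunc_end = trunc_end)
}

#' Extract putative proteins for a table of hits
#'
#' Vectorised companion of [extract_putative_protein()].
#'
#' @param hits an `sp_hits` table from [find_sp_hits()].
#' @param pps the PP collection the hits refer to; defaults to the one
#'   recorded on `hits`.
#' @return a data frame with one row per hit: `source_id`, `frame`, `sp`,
#'   `ec`, `sequence`, `sp_offset`, `length`, `trunc_start`, `trunc_end`.
#' @export
extract_putative_proteins <- function(hits, pps = attr(hits, "pps")) {
  stopifnot(inherits(hits, "sp_hits"))
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    p <- extract_putative_protein(pps$sequence[hits$pp[k]],
                                  hits$offset[k], nchar(hits$sp[k]))
    data.frame(source_id = hits$source_id[k], frame = hits$frame[k],
               sp = hits$sp[k], ec = hits$ec[k], sequence = p$sequence,
               sp_offset = p$sp_offset, length = nchar(p$sequence),
               trunc_start = p$trunc_start, trunc_end = p$trunc_end,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(0), frame = integer(0),
               sp = character(0), ec = character(0), sequence = character(0),
               sp_offset = integer(0), length = integer(0),
               trunc_start = logical(0), trunc_end = logical(0))
  rownames(out) <- NULL
  out
}

#' Leading SP of an EC
#'
#' The leading SP of an EC is the one observed on the largest number of
#' distinct PPs; it defines the group used for counting, since two
#' different SPs of one EC can sit on the same gene. Ties are broken
#' lexicographically by peptide.
#'
#' @param hits an `sp_hits` table.
#' @param ec EC string to restrict to.
#' @return a list with `peptide`, `ec` and `n_pp` (distinct PPs hit).
#' @export
select_leading_sp <- function(hits, ec) {
  stopifnot(inherits(hits, "sp_hits"))
  h <- hits[hits$ec == ec, , drop = FALSE]
  if (!nrow(h)) stop("no hits recorded for EC ", ec)
  tab <- vapply(split(h$pp, h$sp), function(x) length(unique(x)),
                integer(1))
  tab <- tab[order(-tab, names(tab))]
  list(peptide = names(tab)[1L], ec = ec, n_pp = unname(tab[1L]))
}

#' Group SP hits into anchored sets
#'
#' For every SP with at least one hit, collects the hit PPs as an
#' [anchored_set()] anchored at the hit offsets. When counting taxa for
#' one EC only the leading SP's group should be used (see
#' [select_leading_sp()]); all groups are returned so that non-leading
#' sequences remain available for [aggregate_lower_bound()].
#'
#' @param hits an `sp_hits` table.
#' @param pps the PP collection; defaults to the one recorded on `hits`.
#' @return named list mapping each SP peptide to an `anchored_set`. PP
#'   ids are `source_id` for frameless input and `source_id:frame`
#'   otherwise.
#' @export
group_by_sp <- function(hits, pps = attr(hits, "pps")) {
  stopifnot(inherits(hits, "sp_hits"))
  if (!nrow(hits)) return(list())
  out <- lapply(split(seq_len(nrow(hits)), hits$sp), function(idx) {
    h <- hits[idx, , drop = FALSE]
    ids <- ifelse(is.na(h$frame), h$source_id,
                  paste0(h$source_id, ":", sprintf("%+d", h$frame)))
    anchored_set(ids, pps$sequence[h$pp], h$offset, sp = h$sp[1L])
  })
  out[order(names(out))]
}

#' Full counting pipeline: reads to per-EC taxa counts
#'
#' Convenience wrapper chaining translation (for nucleotide input), SP
#' search, leading-SP grouping and heuristic counting, independently per
#' EC.
#'
#' @param reads named character vector of reads/contigs, or an
#'   `anchored_set`-like amino-acid collection.
#' @param table an `sp_table`.
#' @param type `"auto"`, `"nt"` or `"aa"`; `"auto"` treats sequences
#'   consisting only of `A C G T N` letters as nucleotide.
#' @param ec optional character vector restricting the ECs analysed.
#' @return named list per EC: `sp` (leading peptide), `group` (the
#'   leading anchored set) and `result` (a `taxa_count`).
#' @export
run_taxa_pipeline <- function(reads, table, type = c("auto", "nt", "aa"),
                              ec = NULL) {
  type <- match.arg(type)
  if (type == "auto")
    type <- if (all(grepl("^[ACGTN]*$", toupper(reads)))) "nt" else "aa"
  pps <- if (type == "nt") six_frame_translate(reads) else reads
  hits <- find_sp_hits(pps, table)
  if (!nrow(hits)) return(list())
  ecs <- ec %||% sort(unique(hits$ec))
  groups <- group_by_sp(hits)
  out <- lapply(ecs, function(e) {
    lead <- select_leading_sp(hits, e)
    grp <- groups[[lead$peptide]]
    list(sp = lead$peptide, group = grp,
         result = count_taxa_heuristic(grp))
  })
  names(out) <- ecs
  out
}
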