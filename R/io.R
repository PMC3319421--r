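#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases
#' sequences, maps the rare residues `U`/`O` to `X`, keeps FASTQ
#' qualities, and enforces unique record ids (the first whitespace token
#' of each header).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return named character vector of sequences; FASTQ quality strings, if
#'   any, are kept in attribute `quality`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  if (file.exists(path) && file.size(path) == 0L) {
    warning("empty sequence file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- stats::setNames(normalize_aa(as.character(set)), ids)
  if (format == "fastq") {
    q <- S4Vectors::mcols(set)$qualities
    if (!is.null(q)) attr(out, "quality") <- stats::setNames(
      as.character(q), ids)
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Specific-peptide look-up tables
#'
#' An `sp_table` holds marker peptides with their EC assignment, filtered
#' to a minimal length (default 9 residues, below which random hits stop
#' being negligible on short reads).
#'
#' @param peptide amino-acid words over the 20-letter alphabet.
#' @param ec dotted 4-level EC strings, e.g. `"6.1.1.12"`.
#' @param min_length drop peptides shorter than this.
#' @return a data frame of class `sp_table` with columns `peptide`, `ec`,
#'   `length` and attribute `min_length`.
#' @export
sp_table <- function(peptide, ec, min_length = 9L) {
  peptide <- toupper(as.character(peptide))
  ec <- as.character(ec)
  stopifnot(length(peptide) == length(ec))
  bad <- !is_aa20(peptide)
  if (any(bad))
    stop("peptide(s) with non-amino-acid characters: ",
         paste(peptide[bad], collapse = ", "))
  if (anyDuplicated(peptide)) {
    warning("dropping ", sum(duplicated(peptide)),
            " duplicate peptide(s) from SP table")
    keep <- !duplicated(peptide)
    peptide <- peptide[keep]; ec <- ec[keep]
  }
  len <- nchar(peptide)
  drop <- len < min_length
  if (any(drop))
    message("sp_table: dropped ", sum(drop), " peptide(s) shorter than ",
            min_length, " residues")
  out <- data.frame(peptide = peptide[!drop], ec = ec[!drop],
                    length = len[!drop], stringsAsFactors = FALSE)
  attr(out, "min_length") <- as.integer(min_length)
  class(out) <- c("sp_table", "data.frame")
  out
}

#' Read an SP look-up table
#'
#' Parses a two-column plain-text table (peptide, EC; whitespace or tab
#' separated, `#` comments allowed) into an [sp_table()].
#'
#' @param path input file.
#' @param min_length length threshold applied on load (default 9).
#' @return an `sp_table`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("# marker list", "FYALPQAPQ\t6.1.1.12"), tf)
#' read_sp_table(tf)
#' @export
read_sp_table <- function(path, min_length = 9L) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(sp_table(character(0), character(0),
                                      min_length))
  parts <- strsplit(lines, "[\t ]+")
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad))
    stop("SP table line(s) without a peptide and an EC field: ",
         paste(which(bad), collapse = ", "))
  sp_table(vapply(parts, `[[`, character(1), 1L),
           vapply(parts, `[[`, character(1), 2L), min_length)
}

#' Write an SP table
#'
#' @param table an `sp_table`.
#' @param path output file (two-column TSV).
#' @export
write_sp_table <- function(table, path) {
  utils::write.table(table[, c("peptide", "ec")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- count reports --------------------------------------------------------

report_columns <- c("sp", "ec", "S", "d", "count", "trials", "mean", "sem")

#' Tabulate counting results for reporting
#'
#' Normalises counting outputs into the common report layout with columns
#' `sp`, `ec`, `S`, `d`, `count`, `trials`, `mean`, `sem` (missing fields
#' are `NA`).
#'
#' @param x a `taxa_count`, `count_curve`, `subsample_counts` object or a
#'   data frame already in report layout.
#' @param sp,ec optional annotations attached to every row.
#' @return a data frame in report layout.
#' @export
as_count_report <- function(x, sp = NA_character_, ec = NA_character_) {
  row0 <- function(...) {
    args <- list(...)
    n <- max(1L, if (length(args)) max(lengths(args)) else 0L)
    out <- data.frame(sp = rep(sp, n), ec = rep(ec, n), S = NA_integer_,
                      d = NA_integer_, count = NA_integer_,
                      trials = NA_integer_, mean = NA_real_,
                      sem = NA_real_, stringsAsFactors = FALSE)
    for (nm in names(args)) out[[nm]] <- args[[nm]]
    out
  }
  if (inherits(x, "taxa_count"))
    return(row0(sp = if (is.na(sp)) x$sp else sp, d = 1L,
                count = x$count))
  if (inherits(x, "count_curve"))
    return(row0(d = x$d, count = x$count))
  if (inherits(x, "subsample_counts"))
    return(row0(S = attr(x, "S"), d = x$d, trials = attr(x, "trials"),
                mean = x$mean, sem = x$sem))
  if (is.data.frame(x)) {
    missing <- setdiff(report_columns, names(x))
    for (nm in missing) x[[nm]] <- rep(NA, nrow(x))
    return(x[, report_columns, drop = FALSE])
  }
  stop("cannot convert object of class ", class(x)[1L],
       " to a count report")
}

#' Write a count report
#'
#' Writes counting results as a TSV with a fixed, deterministic column
#' order; [read_count_report()] round-trips it losslessly.
#'
#' @param results a single result object or list of them (see
#'   [as_count_report()]).
#' @param path output file.
#' @export
write_count_report <- function(results, path) {
  if (inherits(results, c("taxa_count", "count_curve",
                          "subsample_counts")) || is.data.frame(results))
    results <- list(results)
  rows <- do.call(rbind, lapply(results, as_count_report))
  if (is.null(rows))
    rows <- as_count_report(data.frame())
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write count report to ", path)
  invisible(path)
}

#' Read a count report written by [write_count_report()]
#'
#' @param path input TSV.
#' @return data frame in report layout.
#' @export
read_count_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "integer",
                                   "numeric", "numeric"),
                    stringsAsFactors = FALSE)
}

# --- region annotations ---------------------------------------------------

#' Genic/intergenic region annotations
#'
#' Intervals partitioning a genome into genic and intergenic regions,
#' in 0-based half-open coordinates, with optional EC labels on genic
#' intervals. Used by [evaluate_specificity()].
#'
#' @param seqid sequence (chromosome/contig) ids.
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @param class `"genic"` or `"intergenic"`.
#' @param ec optional EC label per interval (`NA` where absent).
#' @return a data frame of class `region_annotation`.
#' @export
region_annotation <- function(seqid, start, end, class,
                              ec = NA_character_) {
  n <- length(start)
  out <- data.frame(seqid = rep_len(as.character(seqid), n),
                    start = as.integer(start), end = as.integer(end),
                    class = rep_len(as.character(class), n),
                    ec = rep_len(as.character(ec), n),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("region_annotation: intervals must satisfy start < end")
  if (!all(out$class %in% c("genic", "intergenic")))
    stop("region class must be 'genic' or 'intergenic'")
  for (cls in unique(out$class)) {
    sub <- out[out$class == cls, ]
    for (sq in unique(sub$seqid)) {
      iv <- sub[sub$seqid == sq, ]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
        stop("overlapping ", cls, " intervals on ", sq)
    }
  }
  class(out) <- c("region_annotation", "data.frame")
  out
}

#' Read a region annotation from BED or GFF3
#'
#' BED input (`.bed`) is interpreted as 4+ columns with the name field
#' holding the region class, optionally followed by an EC label as
#' `class|EC` (BED is natively 0-based half-open). GFF3 input (`.gff`,
#' `.gff3`) maps features of type `gene`, `CDS` or `mRNA` to genic
#' intervals (EC taken from an `ec=` attribute if present) and features
#' whose type contains `intergenic` to intergenic intervals; 1-based
#' closed coordinates are converted.
#'
#' @param path input file.
#' @return a [region_annotation()].
#' @export
read_region_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("BED annotation needs at least 4 columns")
    name <- strsplit(tab[[4L]], "|", fixed = TRUE)
    cls <- vapply(name, `[[`, character(1), 1L)
    ec <- vapply(name, function(x) if (length(x) > 1L) x[[2L]] else
      NA_character_, character(1))
    return(region_annotation(tab[[1L]], tab[[2L]], tab[[3L]], cls, ec))
  }
  if (ext %in% c("gff", "gff3")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(f, length, integer(1)) < 9L))
      stop("malformed GFF3 line(s) in ", path)
    type <- vapply(f, `[[`, character(1), 3L)
    cls <- ifelse(type %in% c("gene", "CDS", "mRNA"), "genic",
                  ifelse(grepl("intergenic", type), "intergenic",
                         NA_character_))
    keep <- !is.na(cls)
    attrs <- vapply(f, `[[`, character(1), 9L)
    ec <- ifelse(grepl("(^|;)ec=", attrs),
                 sub(".*(^|;)ec=([^;]+).*", "\\2", attrs), NA_character_)
    return(region_annotation(
      vapply(f, `[[`, character(1), 1L)[keep],
      as.integer(vapply(f, `[[`, character(1), 4L))[keep] - 1L,
      as.integer(vapply(f, `[[`, character(1), 5L))[keep],
      cls[keep], ec[keep]))
  }
  stop("unrecognised annotation format: ", path,
       " (expected .bed, .gff or .gff3)")
}

#' Write a region annotation as BED
#'
#' @param annotation a [region_annotation()].
#' @param path output `.bed` file.
#' @export
write_region_annotation <- function(annotation, path) {
  name <- ifelse(is.na(annotation$ec), annotation$class,
                 paste0(annotation$class, "|", annotation$ec))
  utils::write.table(
    data.frame(annotation$seqid, annotation$start, annotation$end, name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
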