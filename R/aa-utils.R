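# Internal amino-acid helpers shared across modules.
#
# Conventions used throughout the package:
#  * anchors and hit offsets are 0-based;
#  * 'X' is an ambiguity wildcard: it matches any residue in consistency
#    checks, is excluded from Hamming counts, and is overwritten by any
#    concrete residue during fusion;
#  * '*' denotes a translation stop and behaves like an ordinary
#    (mismatching) symbol.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# integer codes: 0 = wildcard 'X' (and uncovered positions in anchored
# matrices), 1..20 = the standard residues, 21 = stop, 22+ = rare extended
# letters kept distinct so that they mismatch everything but themselves.
.aa_codes <- local({
  extra <- c("*", "B", "Z", "J")
  codes <- c(seq_along(AA20), 20L + seq_along(extra), 0L)
  names(codes) <- c(AA20, extra, "X")
  codes
})

aa_encode <- function(chars) {
  codes <- .aa_codes[chars]
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("unknown amino-acid symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(codes)
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_aa20 <- function(x) {
  grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), x)
}

# Map lowercase and non-standard residues onto the package alphabet.
# U (selenocysteine) and O (pyrrolysine) become 'X' so that they never
# produce a spurious SP match.
normalize_aa <- function(x) {
  x <- toupper(x)
  x <- chartr("UO", "XX", x)
  x
}

sample_aa <- function(n) sample(AA20, n, replace = TRUE)

# Substitute each residue independently with probability p by a uniformly
# chosen *different* residue of the 20-letter alphabet. Non-standard
# symbols ('X', '*') are left untouched.
mutate_aa <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- split1(seq)
  eligible <- chars %in% AA20
  hit <- eligible & (stats::runif(length(chars)) < p)
  if (any(hit)) {
    idx <- which(hit)
    old <- match(chars[idx], AA20)
    # uniform over the 19 alternatives
    shift <- sample.int(19L, length(idx), replace = TRUE)
    chars[idx] <- AA20[((old - 1L + shift) %% 20L) + 1L]
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
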