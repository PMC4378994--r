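#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the {A,C,G,T,N} alphabet.
#' Lowercase input is uppercased; U is normalized to T first.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_dna(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Normalize a nucleotide string to uppercase DNA
#'
#' Uppercases and converts U to T so RNA-alphabet input (miRBase mature
#' sequences, 3'UTR files) can be handled uniformly.
#'
#' @param x character vector.
#' @return character vector over {A,C,G,T,N}.
#' @export
normalize_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

#' GC fraction of a sequence
#'
#' @param x a single nucleotide string.
#' @return fraction of G+C bases among non-N bases.
#' @export
gc_fraction <- function(x) {
  x <- normalize_dna(x)
  b <- strsplit(x, "", fixed = TRUE)[[1L]]
  b <- b[b != "N"]
  if (length(b) == 0L) return(NA_real_)
  sum(b == "G" | b == "C") / length(b)
}

# Hamming distance between two equal-length strings; N mismatches everything
# (including another N) -- the conservative rule used throughout alignment.
hamming_n <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n <- charToRaw("N")
  sum(ra != rb | ra == n | rb == n)
}

# Phred+33 decoding/encoding for quality strings.
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

phred_encode <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1L))
}

# Mean Phred score per quality string (NA for empty strings).
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0L) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1L), USE.NAMES = FALSE)
}

# Random DNA string(s) from the current RNG stream.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}
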