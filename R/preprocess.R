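# Read preprocessing: quality filtering, 3' end trimming, adapter removal
# and artifact classification, mirroring the pre-alignment stage of the
# small RNA-seq protocol.

#' Mean-quality read filter
#'
#' A read is dropped when its arithmetic mean Phred score falls below
#' \code{cfg$min_mean_quality} (Q20 by default).
#'
#' @param qual character vector of Phred+33 quality strings.
#' @param cfg a \code{pipeline_config}.
#' @return logical vector, TRUE = keep.
#' @export
filter_quality <- function(qual, cfg = pipeline_config()) {
  m <- mean_phred(qual)
  !is.na(m) & m >= cfg$min_mean_quality
}

#' Trim low-quality 3' ends
#'
#' Removes bases from the 3' end while their quality is below
#' \code{cfg$min_mean_quality}. 5' bases are never trimmed: the 5' end of a
#' small RNA defines the biological molecule boundary and must be preserved
#' for isoform-end statistics. A fully low-quality read becomes a length-0
#' read so the downstream dimer/length filters can classify it.
#'
#' @param seq,qual parallel character vectors (sequences and Phred+33
#'   qualities).
#' @param cfg a \code{pipeline_config}.
#' @return list with trimmed \code{seq} and \code{qual}.
#' @export
trim_ends <- function(seq, qual, cfg = pipeline_config()) {
  thr <- cfg$min_mean_quality
  keep_len <- vapply(qual, function(q) {
    s <- utf8ToInt(q) - 33L
    good <- which(s >= thr)
    if (length(good) == 0L) 0L else good[length(good)]
  }, integer(1L), USE.NAMES = FALSE)
  list(seq = substr(seq, 1L, keep_len), qual = substr(qual, 1L, keep_len))
}

# Leftmost adapter-prefix occurrence in one read. Overlap >= min_overlap,
# at most 1 mismatch per `per` matched adapter bases. Returns the 1-based
# position of the adapter start, or 0L when no acceptable occurrence exists.
find_adapter <- function(seq, adapter, min_overlap, per) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  if (n < min_overlap) return(0L)
  rs <- charToRaw(seq)
  ra <- charToRaw(adapter)
  for (p in seq_len(n - min_overlap + 1L)) {
    ov <- min(alen, n - p + 1L)
    allowed <- ov %/% per
    mm <- sum(rs[p:(p + ov - 1L)] != ra[seq_len(ov)])
    if (mm <= allowed) return(p)
  }
  0L
}

# TRUE when >= frac of the insert's bases are one nucleotide.
is_homopolymer <- function(seq, frac) {
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return(FALSE)
    b <- charToRaw(s)
    max(tabulate(as.integer(b), nbins = 256L)) / length(b) >= frac
  }, logical(1L), USE.NAMES = FALSE)
}

#' Trim the 3' adapter and classify the insert
#'
#' Finds the leftmost occurrence of an adapter prefix (minimum overlap
#' \code{cfg$adapter_min_overlap} nt, at most one mismatch per
#' \code{cfg$adapter_mismatch_per} matched adapter bases) and removes it
#' together with everything 3' of it. The remaining insert is classified:
#' length 0 = \code{dimer}; near-mononucleotide insert = \code{homopolymer};
#' shorter than \code{cfg$min_read_len} = \code{too_short}; otherwise
#' \code{clean}.
#'
#' @param seq character vector of read sequences.
#' @param adapter 3' adapter sequence (non-empty).
#' @param cfg a \code{pipeline_config}.
#' @param qual optional parallel quality strings, trimmed alongside.
#' @return list with \code{seq}, \code{qual} (or NULL), and \code{class}
#'   (factor with levels clean, dimer, homopolymer, too_short).
#' @export
trim_adapter <- function(seq, adapter, cfg = pipeline_config(), qual = NULL) {
  if (nchar(adapter) == 0L) stop("adapter must be non-empty")
  adapter <- normalize_dna(adapter)
  pos <- vapply(seq, find_adapter, integer(1L), adapter = adapter,
                min_overlap = cfg$adapter_min_overlap,
                per = cfg$adapter_mismatch_per, USE.NAMES = FALSE)
  ins_end <- ifelse(pos > 0L, pos - 1L, nchar(seq))
  out_seq <- substr(seq, 1L, ins_end)
  out_qual <- if (is.null(qual)) NULL else substr(qual, 1L, ins_end)
  len <- nchar(out_seq)
  cls <- rep("clean", length(seq))
  cls[len < cfg$min_read_len] <- "too_short"
  cls[len > 0L & is_homopolymer(out_seq, cfg$homopolymer_frac)] <- "homopolymer"
  cls[len == 0L] <- "dimer"
  list(seq = out_seq, qual = out_qual,
       class = factor(cls, levels = c("clean", "dimer", "homopolymer",
                                      "too_short")))
}

#' Preprocess a small RNA library
#'
#' Applies, in order, the mean-quality filter, 3' end trimming, and adapter
#' trimming with artifact classification, and tallies a conserved summary
#' (every raw read lands in exactly one bucket).
#'
#' @param reads data.frame with \code{read_id}, \code{seq}, \code{qual}
#'   (as from \code{\link{read_fastq}}), or a FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{reads} (clean reads data.frame) and
#'   \code{summary} (named counts: n_raw, n_quality_fail, n_dimer,
#'   n_homopolymer, n_too_short, n_clean).
#' @export
preprocess_library <- function(reads, adapter, cfg = pipeline_config()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("malformed FASTQ record at row ",
         which(nchar(reads$seq) != nchar(reads$qual))[1L],
         ": sequence and quality lengths differ")
  reads$seq <- normalize_dna(reads$seq)
  n_raw <- nrow(reads)
  keep <- filter_quality(reads$qual, cfg)
  n_quality_fail <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) > 0L) {
    tr <- trim_ends(reads$seq, reads$qual, cfg)
    ta <- trim_adapter(tr$seq, adapter, cfg, qual = tr$qual)
    reads$seq <- ta$seq
    reads$qual <- ta$qual
    cls <- ta$class
  } else {
    cls <- factor(character(0L),
                  levels = c("clean", "dimer", "homopolymer", "too_short"))
  }
  tab <- table(cls)
  clean <- reads[cls == "clean", , drop = FALSE]
  rownames(clean) <- NULL
  summary <- c(n_raw = n_raw,
               n_quality_fail = n_quality_fail,
               n_dimer = unname(tab[["dimer"]]),
               n_homopolymer = unname(tab[["homopolymer"]]),
               n_too_short = unname(tab[["too_short"]]),
               n_clean = unname(tab[["clean"]]))
  list(reads = clean, summary = summary)
}
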