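#' Pipeline configuration
#'
#' Collects every numeric threshold used by the moRNA discovery pipeline in
#' one validated object. Defaults follow the published analysis protocol the
#' pipeline reimplements.
#'
#' @param min_mean_quality minimum mean base quality (Phred) for a read to
#'   survive quality filtering. Default 20.
#' @param min_read_len minimum insert length in nt after trimming. Default 14.
#' @param max_mismatches maximum mismatches allowed in genome alignment.
#'   Default 2.
#' @param max_loci maximum number of genomic placements before a read is
#'   discarded as a multimapper. Default 10.
#' @param flank width in nt of the hairpin flanks searched for offset reads.
#'   Default 30.
#' @param locus_extension nt added on each side of a mature/modal locus when
#'   counting reads against it. Default 2.
#' @param quant_mismatches mismatch tolerance used when quantifying a moRNA
#'   against its reference isomoR locus: 0 for exact-match tables, 2 for
#'   differential-expression style counting. Default 0.
#' @param minor_arm_min_reads minimum read support for a novel minor-arm
#'   miRNA candidate. Default 10.
#' @param minor_arm_min_pairs minimum paired bases between candidate and
#'   known mature within the duplex window. Default 14.
#' @param minor_arm_window duplex window in nt (candidate 5' end anchored).
#'   Default 20.
#' @param novel_min_reads minimum exactly-mapping reads on the main product
#'   of a novel hairpin candidate. Default 10.
#' @param novel_max_copies maximum genomic copies of a novel hairpin.
#'   Default 10.
#' @param gc_bounds allowed GC-content range for novel hairpins. Default
#'   c(0.15, 0.90).
#' @param conservation_threshold mean per-base conservation score above which
#'   (strictly) a locus is called conserved. Default 0.5.
#' @param de_min_rpm minimum RPM in at least one library for inclusion in an
#'   exported count matrix. Default 1.0.
#' @param sizedist_min_reads,sizedist_min_rpm per-library filters (>= 5
#'   reads, >= 0.5 RPM) applied before length-distribution summaries.
#' @param corr_min_rpm both members of a miR/moR pair must exceed this RPM to
#'   enter the correlation. Default 0.5.
#' @param seed_span 1-based positions of the small RNA used as the seed.
#'   Default c(2, 8), i.e. a 7-mer.
#' @param adapter_min_overlap minimum adapter prefix overlap in nt for
#'   3' adapter trimming. Default 5.
#' @param adapter_mismatch_per one mismatch is allowed per this many matched
#'   adapter bases. Default 7.
#' @param homopolymer_frac an insert whose most common base reaches this
#'   fraction is classed a homopolymer artifact. Default 0.9.
#' @param wobble_pairs logical; count G:U wobble as a paired base in duplex
#'   scoring. Default TRUE.
#' @param rpm_denominator "genome" (reads mapped to the genome with up to
#'   \code{max_mismatches}) or "exact" (zero-mismatch mappers only).
#' @param exact_copies logical; if TRUE genomic copy counting for novel
#'   hairpins requires exact copies instead of <= 2 mismatches.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(min_mean_quality = 20,
                            min_read_len = 14L,
                            max_mismatches = 2L,
                            max_loci = 10L,
                            flank = 30L,
                            locus_extension = 2L,
                            quant_mismatches = 0L,
                            minor_arm_min_reads = 10L,
                            minor_arm_min_pairs = 14L,
                            minor_arm_window = 20L,
                            novel_min_reads = 10L,
                            novel_max_copies = 10L,
                            gc_bounds = c(0.15, 0.90),
                            conservation_threshold = 0.5,
                            de_min_rpm = 1.0,
                            sizedist_min_reads = 5L,
                            sizedist_min_rpm = 0.5,
                            corr_min_rpm = 0.5,
                            seed_span = c(2L, 8L),
                            adapter_min_overlap = 5L,
                            adapter_mismatch_per = 7L,
                            homopolymer_frac = 0.9,
                            wobble_pairs = TRUE,
                            rpm_denominator = c("genome", "exact"),
                            exact_copies = FALSE) {
  rpm_denominator <- match.arg(rpm_denominator)
  cfg <- list(
    min_mean_quality = min_mean_quality,
    min_read_len = as.integer(min_read_len),
    max_mismatches = as.integer(max_mismatches),
    max_loci = as.integer(max_loci),
    flank = as.integer(flank),
    locus_extension = as.integer(locus_extension),
    quant_mismatches = as.integer(quant_mismatches),
    minor_arm_min_reads = as.integer(minor_arm_min_reads),
    minor_arm_min_pairs = as.integer(minor_arm_min_pairs),
    minor_arm_window = as.integer(minor_arm_window),
    novel_min_reads = as.integer(novel_min_reads),
    novel_max_copies = as.integer(novel_max_copies),
    gc_bounds = as.numeric(gc_bounds),
    conservation_threshold = conservation_threshold,
    de_min_rpm = de_min_rpm,
    sizedist_min_reads = as.integer(sizedist_min_reads),
    sizedist_min_rpm = sizedist_min_rpm,
    corr_min_rpm = corr_min_rpm,
    seed_span = as.integer(seed_span),
    adapter_min_overlap = as.integer(adapter_min_overlap),
    adapter_mismatch_per = as.integer(adapter_mismatch_per),
    homopolymer_frac = homopolymer_frac,
    wobble_pairs = isTRUE(wobble_pairs),
    rpm_denominator = rpm_denominator,
    exact_copies = isTRUE(exact_copies)
  )
  counts <- c("min_read_len", "max_mismatches", "max_loci", "flank",
              "locus_extension", "quant_mismatches", "minor_arm_min_reads",
              "minor_arm_min_pairs", "minor_arm_window", "novel_min_reads",
              "novel_max_copies", "sizedist_min_reads")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("config field '", nm, "' must be a non-negative count")
  }
  if (length(cfg$gc_bounds) != 2L || any(cfg$gc_bounds < 0) ||
      any(cfg$gc_bounds > 1) || cfg$gc_bounds[1L] > cfg$gc_bounds[2L])
    stop("gc_bounds must be an increasing pair within [0, 1]")
  if (length(cfg$seed_span) != 2L ||
      diff(cfg$seed_span) + 1L != 7L)
    stop("seed_span must cover exactly 7 positions")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("moRNA pipeline configuration\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ", "),
                 character(1L))
  cat(sprintf("  %-22s %s\n", names(flat), flat), sep = "")
  invisible(x)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines of the form \code{key = value} (or \code{key: value}); keys mirror
#' the \code{\link{pipeline_config}} arguments. Pair-valued fields
#' (\code{gc_bounds}, \code{seed_span}) take comma-separated values.
#'
#' @param path file path.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) < 2L) stop("malformed config line: ", paste(p, collapse = ""))
    key <- trimws(p[[1L]])
    val <- trimws(paste(p[-1L], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (!anyNA(num)) num else if (
      all(toupper(parts) %in% c("TRUE", "FALSE"))) as.logical(toupper(parts)) else parts
  }
  do.call(pipeline_config, args)
}
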