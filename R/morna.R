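# The moRNA caller: collect offset reads from hairpin flanks, group
# isoforms (isomoRs), pick the most abundant isomoR as the reference,
# quantify against its locus, and derive the descriptive statistics.

overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Collect candidate offset reads from hairpin flanks
#'
#' A genome-aligned read becomes a (hairpin, 5p) moRNA candidate when its
#' interval lies within the extended hairpin locus, is not fully contained
#' in the hairpin itself, overlaps the 5' flank by more nucleotides than it
#' overlaps the hairpin, and is on the precursor's strand; symmetrically
#' for 3p. Reads spilling 1-2 nt into the mature miRNA therefore remain
#' eligible. Reads in the shared gap between clustered hairpins join every
#' eligible hairpin's candidate set.
#'
#' @param alignments alignment data.frame from \code{\link{align_reads}}.
#' @param ext_hairpins named list of \code{extended_hairpin}.
#' @param cfg a \code{pipeline_config}.
#' @return data.frame: hairpin, arm, seq, chrom, start, end, strand,
#'   mismatches (one row per sequence placement per hairpin arm).
#' @export
collect_offset_reads <- function(alignments, ext_hairpins,
                                 cfg = pipeline_config()) {
  out <- list()
  for (eh in ext_hairpins) {
    hp <- eh$hairpin
    sel <- alignments$chrom == hp$chrom & alignments$strand == hp$strand &
      alignments$start >= eh$ext_start & alignments$end <= eh$ext_end
    if (!any(sel)) next
    a <- alignments[sel, , drop = FALSE]
    inside_hp <- a$start >= hp$start & a$end <= hp$end
    a <- a[!inside_hp, , drop = FALSE]
    if (nrow(a) == 0L) next
    ov_hp <- overlap_len(a$start, a$end, hp$start, hp$end)
    f5 <- region_interval(eh, "moR5p")
    f3 <- region_interval(eh, "moR3p")
    ov_f5 <- if (nrow(f5) > 0L)
      overlap_len(a$start, a$end, f5$start, f5$end) else 0L
    ov_f3 <- if (nrow(f3) > 0L)
      overlap_len(a$start, a$end, f3$start, f3$end) else 0L
    for (arm in c("5p", "3p")) {
      keep <- if (arm == "5p") ov_f5 > ov_hp else ov_f3 > ov_hp
      if (!any(keep)) next
      cand <- a[keep, , drop = FALSE]
      cand$hairpin <- hp$name
      cand$arm <- arm
      # a sequence placed more than once within one flank would double-count
      # its multiplicity: keep the transcript-5'-most placement
      if (anyDuplicated(cand$seq)) {
        tstart <- if (hp$strand == "+") cand$start else -cand$end
        cand <- cand[order(cand$seq, cand$mismatches, tstart), , drop = FALSE]
        cand <- cand[!duplicated(cand$seq), , drop = FALSE]
      }
      out[[length(out) + 1L]] <-
        cand[, c("hairpin", "arm", "seq", "chrom", "start", "end",
                 "strand", "mismatches")]
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(hairpin = character(0L), arm = character(0L),
               seq = character(0L), chrom = character(0L),
               start = integer(0L), end = integer(0L),
               strand = character(0L), mismatches = integer(0L))
  rownames(res) <- NULL
  res
}

# Deterministic modal-member selection: maximal total multiplicity, ties
# broken by longer sequence, then transcript-5'-most start, then
# lexicographically smallest sequence.
modal_index <- function(members) {
  tstart <- ifelse(members$strand == "+", members$start, -members$end)
  ord <- order(-members$count, -nchar(members$seq), tstart, members$seq)
  ord[1L]
}

#' Group candidate offset reads into isomoR groups
#'
#' One group per (hairpin, arm) with at least one candidate read. The
#' group's modal sequence is the distinct aligned sequence with maximal
#' total read multiplicity (ties: longer sequence, then 5'-most start in
#' transcript orientation, then lexicographic).
#'
#' @param candidates data.frame from \code{\link{collect_offset_reads}}.
#' @param counts_total named numeric vector: total multiplicity (across
#'   libraries) per read sequence.
#' @return list of \code{iso_group} objects (fields: hairpin, arm, members
#'   data.frame with per-sequence counts, modal_seq, modal_locus).
#' @export
group_isoforms <- function(candidates, counts_total) {
  if (nrow(candidates) == 0L) return(list())
  key <- paste(candidates$hairpin, candidates$arm, sep = "\r")
  groups <- split(candidates, key)
  out <- lapply(groups, function(g) {
    g$count <- unname(counts_total[g$seq])
    g$count[is.na(g$count)] <- 0
    g <- g[g$count > 0, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    i <- modal_index(g)
    structure(list(hairpin = g$hairpin[1L], arm = g$arm[1L],
                   members = g[, c("seq", "chrom", "start", "end", "strand",
                                   "mismatches", "count")],
                   modal_seq = g$seq[i],
                   modal_locus = list(chrom = g$chrom[i], start = g$start[i],
                                      end = g$end[i], strand = g$strand[i])),
              class = "iso_group")
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  names(out) <- vapply(out, function(g) paste0(g$hairpin, ":", g$arm),
                       character(1L))
  out[order(names(out))]
}

#' @export
print.iso_group <- function(x, ...) {
  cat(sprintf("<isomoR group %s %s: %d unique seqs, %d reads, modal %s>\n",
              x$hairpin, x$arm, nrow(x$members), round(sum(x$members$count)),
              x$modal_seq))
  invisible(x)
}

#' 5'-end consistency of an isomoR group
#'
#' Multiplicity-weighted fraction of the group's reads that share the modal
#' 5'-end position (5' taken in transcript orientation).
#'
#' @param group an \code{iso_group}.
#' @return fraction in [0, 1].
#' @export
five_prime_consistency <- function(group) {
  m <- group$members
  if (nrow(m) == 0L) stop("empty isomoR group")
  five <- ifelse(m$strand == "+", m$start, m$end)
  tab <- tapply(m$count, five, sum)
  max(tab) / sum(tab)
}

#' Quantify a moRNA against its reference isomoR locus
#'
#' Per library, counts the multiplicity of reads whose aligned interval is
#' contained in the modal (reference) locus widened by
#' \code{cfg$locus_extension} nt on each side, same strand, with at most
#' \code{cfg$quant_mismatches} mismatches (0 for exact-match reporting, 2
#' for differential-expression style counting).
#'
#' @param group an \code{iso_group}.
#' @param alignments the full alignment table of the experiment.
#' @param lib_counts per-library multiplicity matrix, rows named by read
#'   sequence.
#' @param denominators named per-library mapping totals for RPM.
#' @param cfg a \code{pipeline_config}.
#' @return object of class \code{morna_call}: name, hairpin, arm, ref_seq,
#'   ref_locus, counts, rpm, n_unique_isomors, five_prime_consistency,
#'   length_histogram.
#' @export
quantify_morna <- function(group, alignments, lib_counts, denominators,
                           cfg = pipeline_config()) {
  loc <- group$modal_locus
  ext <- cfg$locus_extension
  sel <- alignments$chrom == loc$chrom & alignments$strand == loc$strand &
    alignments$start >= loc$start - ext & alignments$end <= loc$end + ext &
    alignments$mismatches <= cfg$quant_mismatches
  seqs <- unique(alignments$seq[sel])
  seqs <- seqs[seqs %in% rownames(lib_counts)]
  counts <- if (length(seqs) > 0L)
    colSums(lib_counts[seqs, , drop = FALSE])
  else stats::setNames(numeric(ncol(lib_counts)), colnames(lib_counts))
  rpm <- counts / denominators[names(counts)] * 1e6
  lens <- tapply(group$members$count, nchar(group$members$seq), sum)
  structure(list(name = morna_name(group$hairpin, group$arm),
                 hairpin = group$hairpin, arm = group$arm,
                 ref_seq = group$modal_seq, ref_locus = loc,
                 counts = counts, rpm = rpm,
                 n_unique_isomors = nrow(group$members),
                 five_prime_consistency = five_prime_consistency(group),
                 length_histogram = lens),
            class = "morna_call")
}

#' @export
print.morna_call <- function(x, ...) {
  cat(sprintf("<moRNA call %s: ref %s (%s:%d-%d%s), %d isomoRs, 5'cons %.2f>\n",
              x$name, x$ref_seq, x$ref_locus$chrom, x$ref_locus$start,
              x$ref_locus$end, x$ref_locus$strand, x$n_unique_isomors,
              x$five_prime_consistency))
  print(rbind(count = x$counts, rpm = round(x$rpm, 2)))
  invisible(x)
}

#' Flatten a list of moRNA calls into a table
#'
#' @param calls list of \code{morna_call}.
#' @return data.frame, one row per call, with per-library \code{count.*}
#'   and \code{rpm.*} columns.
#' @export
morna_call_table <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(name = character(0L), hairpin = character(0L),
                      arm = character(0L), ref_seq = character(0L)))
  rows <- lapply(calls, function(x) {
    d <- data.frame(name = x$name, hairpin = x$hairpin, arm = x$arm,
                    ref_seq = x$ref_seq, chrom = x$ref_locus$chrom,
                    start = x$ref_locus$start, end = x$ref_locus$end,
                    strand = x$ref_locus$strand,
                    n_unique_isomors = x$n_unique_isomors,
                    five_prime_consistency = x$five_prime_consistency,
                    stringsAsFactors = FALSE)
    for (lib in names(x$counts)) d[[paste0("count.", lib)]] <- x$counts[[lib]]
    for (lib in names(x$rpm)) d[[paste0("rpm.", lib)]] <- x$rpm[[lib]]
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Library-level moRNA statistics
#'
#' Arm usage and length distributions. \code{arm_fraction_5p} is the
#' fraction of all candidate moRNA read multiplicity derived from the 5'
#' arm, per library and pooled. Length distributions pool isomoR read
#' lengths (multiplicity-weighted) over the calls that pass the
#' per-library size-distribution filters (at least
#' \code{cfg$sizedist_min_reads} reads and \code{cfg$sizedist_min_rpm} RPM).
#'
#' @param groups list of \code{iso_group}.
#' @param calls list of \code{morna_call} (parallel to groups).
#' @param lib_counts per-library multiplicity matrix.
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{arm_fraction_5p} (named vector per library plus
#'   "pooled"), \code{arm_reads} (library x arm matrix), and
#'   \code{length_dist} (list mor5p/mor3p of named count vectors).
#' @export
morna_stats <- function(groups, calls, lib_counts,
                        cfg = pipeline_config()) {
  libs <- colnames(lib_counts)
  arm_reads <- matrix(0, nrow = length(libs), ncol = 2L,
                      dimnames = list(libs, c("5p", "3p")))
  for (g in groups) {
    seqs <- g$members$seq[g$members$seq %in% rownames(lib_counts)]
    if (length(seqs) == 0L) next
    arm_reads[, g$arm] <- arm_reads[, g$arm] +
      colSums(lib_counts[seqs, , drop = FALSE])
  }
  totals <- rowSums(arm_reads)
  arm_fraction_5p <- ifelse(totals > 0, arm_reads[, "5p"] / totals, NA_real_)
  pooled <- if (sum(arm_reads) > 0) sum(arm_reads[, "5p"]) / sum(arm_reads)
            else NA_real_
  arm_fraction_5p <- c(arm_fraction_5p, pooled = pooled)

  length_dist <- list(mor5p = integer(0L), mor3p = integer(0L))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    cl <- calls[[i]]
    pass_libs <- names(cl$counts)[cl$counts >= cfg$sizedist_min_reads &
                                    cl$rpm >= cfg$sizedist_min_rpm]
    if (length(pass_libs) == 0L) next
    seqs <- g$members$seq[g$members$seq %in% rownames(lib_counts)]
    if (length(seqs) == 0L) next
    w <- rowSums(lib_counts[seqs, pass_libs, drop = FALSE])
    lens <- nchar(seqs)
    tab <- tapply(w, lens, sum)
    slot <- if (g$arm == "5p") "mor5p" else "mor3p"
    cur <- length_dist[[slot]]
    for (nm in names(tab)) cur[nm] <- (if (nm %in% names(cur)) cur[nm] else 0) + tab[nm]
    length_dist[[slot]] <- cur
  }
  length_dist <- lapply(length_dist, function(v) v[order(as.integer(names(v)))])
  list(arm_fraction_5p = arm_fraction_5p, arm_reads = arm_reads,
       length_dist = length_dist)
}

#' Spearman correlation between miRNA and moRNA expression
#'
#' Pairs where either RPM is at or below \code{cfg$corr_min_rpm} are
#' excluded; the coefficient uses average ranks for ties. With fewer than 3
#' surviving pairs the coefficient is undefined and reported as NA.
#'
#' @param mir_rpm,mor_rpm paired RPM vectors (shared hairpin arm).
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{rho} and \code{n_pairs}.
#' @export
mir_mor_correlation <- function(mir_rpm, mor_rpm, cfg = pipeline_config()) {
  stopifnot(length(mir_rpm) == length(mor_rpm))
  keep <- !is.na(mir_rpm) & !is.na(mor_rpm) &
    mir_rpm > cfg$corr_min_rpm & mor_rpm > cfg$corr_min_rpm
  n <- sum(keep)
  if (n < 3L) return(list(rho = NA_real_, n_pairs = n))
  list(rho = stats::cor(mir_rpm[keep], mor_rpm[keep], method = "spearman"),
       n_pairs = n)
}

#' Export a count matrix for differential expression
#'
#' Keeps features reaching \code{cfg$de_min_rpm} RPM in at least one
#' library; raw integer counts; input row order preserved.
#'
#' @param counts,rpm feature x library matrices with matching dimnames.
#' @param cfg a \code{pipeline_config}.
#' @param file optional TSV output path.
#' @return the filtered integer count matrix (invisibly when written).
#' @export
export_count_matrix <- function(counts, rpm, cfg = pipeline_config(),
                                file = NULL) {
  stopifnot(identical(dim(counts), dim(rpm)))
  keep <- apply(rpm, 1L, function(r) any(r >= cfg$de_min_rpm, na.rm = TRUE))
  out <- counts[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  if (!is.null(file)) {
    df <- data.frame(feature = rownames(out), out, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, file)
    return(invisible(out))
  }
  out
}
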