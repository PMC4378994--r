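# Novel miRNA calling: minor-arm products on known single-arm precursors,
# post-prediction filters for novel hairpin candidates, and conservation
# classification from a per-base score track.

base_pairs_ok <- function(a, b, wobble) {
  # antiparallel base pairing in DNA alphabet: A:T, C:G, plus G:T wobble
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (!wobble) return(wc)
  wc | (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Maximal duplex pairing of a candidate against a known mature
#'
#' Slides the candidate's first \code{window} nt over all ungapped
#' antiparallel registrations against the known mature sequence and returns
#' the maximal number of paired positions. Watson-Crick pairs always count;
#' G:U wobble counts when \code{cfg$wobble_pairs} is on (default).
#'
#' @param candidate,known_mature nucleotide strings (RNA or DNA alphabet).
#' @param cfg a \code{pipeline_config} (window via
#'   \code{cfg$minor_arm_window}).
#' @param window override for the candidate-anchored window, in nt.
#' @return integer, the maximal paired-base count.
#' @export
duplex_pair_count <- function(candidate, known_mature,
                              cfg = pipeline_config(),
                              window = cfg$minor_arm_window) {
  candidate <- normalize_dna(candidate)
  known_mature <- normalize_dna(known_mature)
  if (nchar(candidate) < 1L || nchar(known_mature) < 1L)
    stop("sequences must be non-empty")
  a <- strsplit(substr(candidate, 1L, window), "", fixed = TRUE)[[1L]]
  # antiparallel: candidate 5'->3' against the mature read 3'->5'
  b <- rev(strsplit(known_mature, "", fixed = TRUE)[[1L]])
  la <- length(a); lb <- length(b)
  best <- 0L
  for (off in (-(la - 1L)):(lb - 1L)) {
    i <- seq_len(la)
    j <- i + off
    ok <- j >= 1L & j <= lb
    if (!any(ok)) next
    n <- sum(base_pairs_ok(a[i[ok]], b[j[ok]], cfg$wobble_pairs))
    if (n > best) best <- n
  }
  best
}

#' Call a novel minor-arm miRNA on a single-arm precursor
#'
#' For a hairpin with exactly one annotated mature, the candidate is the
#' modal zero-mismatch read sequence mapping fully within the opposite arm
#' of the precursor. The candidate is accepted when it has at least
#' \code{cfg$minor_arm_min_reads} occurrences, maps with no mismatches, and
#' pairs with the known mature at \code{cfg$minor_arm_min_pairs} or more
#' positions within the candidate's first \code{cfg$minor_arm_window} nt.
#'
#' @param hp a \code{hairpin_record} with exactly one annotated mature.
#' @param alignments alignment data.frame over the experiment.
#' @param counts_total named numeric vector of per-sequence multiplicities.
#' @param cfg a \code{pipeline_config}.
#' @return object of class \code{minor_arm_candidate} (fields: hairpin_name,
#'   candidate_seq, arm, read_support, pair_count, accepted), or NULL when
#'   the hairpin is skipped or no candidate read exists.
#' @export
call_minor_arm <- function(hp, alignments, counts_total,
                           cfg = pipeline_config()) {
  has5 <- !is.null(hp$mature5p)
  has3 <- !is.null(hp$mature3p)
  if (has5 == has3) {
    message("skipping ", hp$name, ": requires exactly one annotated mature")
    return(NULL)
  }
  known_arm <- if (has5) "5p" else "3p"
  new_arm <- if (has5) "3p" else "5p"
  m <- if (has5) hp$mature5p else hp$mature3p
  # opposite arm: the precursor interval on the transcript-3' (resp. -5')
  # side of the known mature
  if (hp$strand == "+") {
    opp <- if (has5) c(m[2L], hp$end) else c(hp$start, m[1L])
  } else {
    opp <- if (has5) c(hp$start, m[1L]) else c(m[2L], hp$end)
  }
  sel <- alignments$chrom == hp$chrom & alignments$strand == hp$strand &
    alignments$mismatches == 0L &
    alignments$start >= opp[1L] & alignments$end <= opp[2L]
  if (!any(sel)) return(NULL)
  cand <- alignments[sel, , drop = FALSE]
  cand <- cand[!duplicated(cand$seq), , drop = FALSE]
  cand$count <- unname(counts_total[cand$seq])
  cand$count[is.na(cand$count)] <- 0
  cand <- cand[cand$count > 0, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  i <- modal_index(cand)
  support <- cand$count[i]
  pair_count <- duplex_pair_count(cand$seq[i], mature_seq(hp, known_arm), cfg)
  structure(list(hairpin_name = hp$name, candidate_seq = cand$seq[i],
                 arm = new_arm, read_support = support,
                 pair_count = pair_count,
                 accepted = support >= cfg$minor_arm_min_reads &&
                   pair_count >= cfg$minor_arm_min_pairs),
            class = "minor_arm_candidate")
}

#' @export
print.minor_arm_candidate <- function(x, ...) {
  cat(sprintf("<minor-arm candidate %s-%s %s: %d reads, %d paired, %s>\n",
              x$hairpin_name, x$arm, x$candidate_seq, round(x$read_support),
              x$pair_count, if (x$accepted) "ACCEPTED" else "rejected"))
  invisible(x)
}

#' Post-prediction filters for a novel hairpin candidate
#'
#' Applies the three acceptance criteria for an externally predicted novel
#' miRNA hairpin: (1) at least \code{cfg$novel_min_reads} exactly-mapping
#' reads on the hairpin's main product, (2) at most
#' \code{cfg$novel_max_copies} genomic copies (full-length placements with
#' up to \code{cfg$max_mismatches} mismatches, or exact copies when
#' \code{cfg$exact_copies}), and (3) GC content within
#' \code{cfg$gc_bounds}. Optionally classifies conservation over the
#' hairpin locus.
#'
#' @param name candidate name.
#' @param hairpin_seq candidate hairpin sequence (sense orientation).
#' @param read_stack data.frame with \code{seq} and \code{count}: the reads
#'   attributed to this candidate.
#' @param genome genome (any form accepted by \code{\link{load_genome}}).
#' @param cfg a \code{pipeline_config}.
#' @param conservation optional track data.frame (chrom, start, end, score).
#' @param locus optional list(chrom, start, end) for the conservation call.
#' @return object of class \code{hairpin_filter_report}: candidate_name,
#'   main_product_reads, main_product_seq, genomic_copies, gc_fraction,
#'   conserved (NA when no track), passed.
#' @export
filter_novel_hairpin <- function(name, hairpin_seq, read_stack, genome,
                                 cfg = pipeline_config(),
                                 conservation = NULL, locus = NULL) {
  hairpin_seq <- normalize_dna(hairpin_seq)
  # main product: the most abundant exactly-matching read sequence
  main_reads <- 0
  main_seq <- NA_character_
  if (nrow(read_stack) > 0L) {
    exact <- vapply(normalize_dna(read_stack$seq), function(s) {
      grepl(s, hairpin_seq, fixed = TRUE)
    }, logical(1L), USE.NAMES = FALSE)
    stack <- read_stack[exact, , drop = FALSE]
    if (nrow(stack) > 0L) {
      agg <- tapply(stack$count, stack$seq, sum)
      main_reads <- max(agg)
      main_seq <- names(agg)[which.max(agg)]
    }
  }
  genome <- load_genome(genome)
  copy_mm <- if (cfg$exact_copies) 0L else cfg$max_mismatches
  copies <- 0L
  rc <- revcomp(hairpin_seq)
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    copies <- copies + nrow(scan_pattern(hairpin_seq, subject, copy_mm)) +
      nrow(scan_pattern(rc, subject, copy_mm))
  }
  gc <- gc_fraction(hairpin_seq)
  conserved <- NA
  cons_mean <- NA_real_
  if (!is.null(conservation) && !is.null(locus)) {
    cc <- conservation_class(locus, conservation, cfg)
    conserved <- cc$conserved
    cons_mean <- cc$mean_score
  }
  passed <- main_reads >= cfg$novel_min_reads &&
    copies <= cfg$novel_max_copies &&
    gc >= cfg$gc_bounds[1L] && gc <= cfg$gc_bounds[2L]
  structure(list(candidate_name = name, main_product_reads = main_reads,
                 main_product_seq = main_seq, genomic_copies = copies,
                 gc_fraction = gc, conserved = conserved,
                 conservation_mean = cons_mean, passed = passed),
            class = "hairpin_filter_report")
}

#' @export
print.hairpin_filter_report <- function(x, ...) {
  cat(sprintf(
    "<novel hairpin %s: main product %s reads, %d copies, GC %.2f, %s%s>\n",
    x$candidate_name, format(x$main_product_reads), x$genomic_copies,
    x$gc_fraction, if (x$passed) "PASSED" else "failed",
    if (is.na(x$conserved)) "" else
      paste0(", ", if (x$conserved) "conserved" else "nonconserved")))
  invisible(x)
}

#' Conservation classification of a genomic interval
#'
#' Mean of per-base conservation scores over the interval; positions not
#' covered by the track score 0 (their number is reported). The locus is
#' conserved when the mean strictly exceeds
#' \code{cfg$conservation_threshold}.
#'
#' @param interval list or one-row data.frame with chrom, start, end
#'   (0-based half-open).
#' @param track data.frame: chrom, start, end, score (bedGraph-style,
#'   0-based half-open).
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{conserved}, \code{mean_score},
#'   \code{n_missing}.
#' @export
conservation_class <- function(interval, track, cfg = pipeline_config()) {
  s <- as.integer(interval$start)
  e <- as.integer(interval$end)
  len <- e - s
  if (is.na(len) || len <= 0L) stop("empty interval")
  rows <- track[track$chrom == interval$chrom & track$end > s &
                  track$start < e, , drop = FALSE]
  ov <- overlap_len(rows$start, rows$end, s, e)
  total <- sum(rows$score * ov)
  covered <- sum(ov)
  mean_score <- total / len
  list(conserved = mean_score > cfg$conservation_threshold,
       mean_score = mean_score,
       n_missing = len - covered)
}
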