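# Ungapped mismatch-tolerant multi-locus alignment and the hierarchical
# ncRNA annotation cascade. Biostrings' mismatch-aware exact search
# (matchPattern with with.indels = FALSE) is the scan engine; placements
# are end-to-end Hamming matches, as with a -v style short-read aligner.

CASCADE_LABELS <- c("mirna_hairpin", "snRNA", "snoRNA", "rRNA", "mt_tRNA",
                    "miscRNA", "piRNA", "tRNA", "repeat")

# All end-to-end placements of `pattern` on the plus strand of `subject`
# (a DNAString) with Hamming distance <= max_mm under the N-as-mismatch
# rule. Returns data.frame(start (0-based), end, mismatches).
scan_pattern <- function(pattern, subject, max_mm) {
  if (nchar(pattern) > length(subject))
    return(data.frame(start = integer(0L), end = integer(0L),
                      mismatches = integer(0L)))
  hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                   with.indels = FALSE, fixed = TRUE)
  # drop out-of-bounds views (overhanging placements are not end-to-end)
  hits <- hits[IRanges::start(hits) >= 1L &
                 IRanges::end(hits) <= length(subject)]
  if (length(hits) == 0L)
    return(data.frame(start = integer(0L), end = integer(0L),
                      mismatches = integer(0L)))
  windows <- as.character(hits)
  mm <- vapply(windows, function(w) hamming_n(pattern, w), integer(1L),
               USE.NAMES = FALSE)
  keep <- mm <= max_mm
  data.frame(start = IRanges::start(hits)[keep] - 1L,
             end = IRanges::end(hits)[keep],
             mismatches = mm[keep])
}

#' Align reads to a reference by ungapped mismatch-tolerant search
#'
#' Every end-to-end placement of each read on either strand with Hamming
#' distance at most \code{cfg$max_mismatches} is reported; minus-strand
#' placements compare the reverse-complemented read. A read with more than
#' \code{cfg$max_loci} placements is discarded and flagged
#' \code{multimapper_overflow}. N bases count as mismatches against every
#' reference base.
#'
#' @param seqs character vector of (unique) read sequences.
#' @param reference named character vector of reference sequences, a
#'   \code{DNAStringSet}, or a FASTA path.
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{alignments} (data.frame: seq, chrom, start, end,
#'   strand, mismatches; 0-based half-open) and \code{status} (data.frame:
#'   seq, status in aligned/unaligned/multimapper_overflow, n_loci).
#' @export
align_reads <- function(seqs, reference, cfg = pipeline_config()) {
  reference <- load_genome(reference)
  subjects <- lapply(reference, Biostrings::DNAString)
  seqs <- normalize_dna(seqs)
  uniq <- unique(seqs)
  aln <- vector("list", length(uniq))
  status <- character(length(uniq))
  n_loci <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    s <- uniq[i]
    rc <- revcomp(s)
    hits <- list()
    for (chrom in names(subjects)) {
      fwd <- scan_pattern(s, subjects[[chrom]], cfg$max_mismatches)
      if (nrow(fwd) > 0L) {
        fwd$chrom <- chrom; fwd$strand <- "+"
        hits[[length(hits) + 1L]] <- fwd
      }
      rev <- scan_pattern(rc, subjects[[chrom]], cfg$max_mismatches)
      if (nrow(rev) > 0L) {
        rev$chrom <- chrom; rev$strand <- "-"
        hits[[length(hits) + 1L]] <- rev
      }
    }
    h <- if (length(hits) > 0L) do.call(rbind, hits) else NULL
    k <- if (is.null(h)) 0L else nrow(h)
    n_loci[i] <- k
    if (k == 0L) {
      status[i] <- "unaligned"
    } else if (k > cfg$max_loci) {
      status[i] <- "multimapper_overflow"
    } else {
      status[i] <- "aligned"
      h$seq <- s
      aln[[i]] <- h[, c("seq", "chrom", "start", "end", "strand",
                        "mismatches")]
    }
  }
  alignments <- do.call(rbind, aln[!vapply(aln, is.null, logical(1L))])
  if (is.null(alignments))
    alignments <- data.frame(seq = character(0L), chrom = character(0L),
                             start = integer(0L), end = integer(0L),
                             strand = character(0L), mismatches = integer(0L))
  rownames(alignments) <- NULL
  list(alignments = alignments,
       status = data.frame(seq = uniq, status = status, n_loci = n_loci,
                           stringsAsFactors = FALSE))
}

# Concatenate class reference sequences into one search subject with an N
# separator wide enough that no window within the mismatch tolerance can
# straddle two references.
make_class_subject <- function(refs, max_mm) {
  sep <- strrep("N", max_mm + 1L)
  Biostrings::DNAString(paste(normalize_dna(refs), collapse = sep))
}

#' Hierarchical ncRNA annotation cascade
#'
#' First-match-wins classification of reads against an ordered set of
#' reference classes. The \code{mirna_hairpin} class (tested first) accepts
#' containment with up to \code{cfg$max_mismatches} mismatches; every other
#' class requires exact (0-mismatch) containment in one of its reference
#' sequences. Reads matching nothing are \code{unannotated}.
#'
#' @param seqs character vector of read sequences.
#' @param class_references ordered named list, label -> character vector of
#'   reference sequences. Labels must come from the known cascade set
#'   (mirna_hairpin, snRNA, snoRNA, rRNA, mt_tRNA, miscRNA, piRNA, tRNA,
#'   repeat).
#' @param cfg a \code{pipeline_config}.
#' @return factor of class labels per read, levels = supplied labels plus
#'   \code{unannotated}.
#' @export
annotate_cascade <- function(seqs, class_references,
                             cfg = pipeline_config()) {
  labels <- names(class_references)
  bad <- setdiff(labels, CASCADE_LABELS)
  if (length(bad) > 0L)
    stop("unknown class label(s) in reference map: ",
         paste(bad, collapse = ", "))
  seqs <- normalize_dna(seqs)
  uniq <- unique(seqs)
  assigned <- rep(NA_character_, length(uniq))
  remaining <- rep(TRUE, length(uniq))
  for (lab in labels) {
    refs <- class_references[[lab]]
    if (lab == "mirna_hairpin" && cfg$max_mismatches > 0L) {
      subject <- make_class_subject(refs, cfg$max_mismatches)
      idx <- which(remaining)
      hit <- vapply(uniq[idx], function(s) {
        nrow(scan_pattern(s, subject, cfg$max_mismatches)) > 0L
      }, logical(1L), USE.NAMES = FALSE)
    } else {
      joined <- paste0("#", paste(normalize_dna(refs), collapse = "#"), "#")
      idx <- which(remaining)
      hit <- vapply(uniq[idx], function(s) {
        grepl(s, joined, fixed = TRUE)
      }, logical(1L), USE.NAMES = FALSE)
    }
    assigned[idx[hit]] <- lab
    remaining[idx[hit]] <- FALSE
  }
  assigned[is.na(assigned)] <- "unannotated"
  factor(assigned[match(seqs, uniq)],
         levels = c(labels, "unannotated"))
}

#' Name a mature miRNA from its precursor
#'
#' Follows the field convention: precursor \code{hsa-mir-103a-2} yields
#' \code{hsa-miR-103a-2-5p} / \code{-3p}. For names without a \code{mir}
#' token the arm suffix is simply appended.
#'
#' @param hairpin_name precursor name.
#' @param arm "5p" or "3p".
#' @return character name.
#' @export
mirna_name <- function(hairpin_name, arm) {
  base <- sub("(^|-)mir-", "\\1miR-", hairpin_name)
  paste0(base, "-", arm)
}

#' Name a moRNA from its precursor
#'
#' Precursor \code{hsa-mir-367} yields \code{hsa-moR-367-3p} etc.
#'
#' @param hairpin_name precursor name.
#' @param arm "5p" or "3p".
#' @return character name.
#' @export
morna_name <- function(hairpin_name, arm) {
  base <- sub("(^|-)mir-", "\\1moR-", hairpin_name)
  if (identical(base, hairpin_name)) base <- paste0(hairpin_name, "-moR")
  paste0(base, "-", arm)
}

#' Count reads on mature miRNA loci with locus extension
#'
#' A read is counted for a mature miRNA when its aligned interval is
#' contained within the mature locus widened by \code{cfg$locus_extension}
#' nt on each side, on the same strand. A read counts toward every mature
#' locus it satisfies (paralogous loci sharing one sequence receive
#' identical counts).
#'
#' @param alignments alignment data.frame (as from \code{\link{align_reads}})
#'   restricted to hairpin-class reads.
#' @param hairpins list of \code{hairpin_record} supplying the mature loci.
#' @param lib_counts numeric matrix of per-library multiplicities, rows
#'   named by read sequence, one column per library.
#' @param denominators named numeric vector, per-library mapping totals for
#'   RPM (see \code{cfg$rpm_denominator}).
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{counts} and \code{rpm}: feature x library
#'   matrices, rows named by mature miRNA.
#' @export
count_mature_mirna <- function(alignments, hairpins, lib_counts,
                               denominators, cfg = pipeline_config()) {
  feats <- list()
  for (hp in hairpins) {
    for (arm in c("5p", "3p")) {
      m <- if (arm == "5p") hp$mature5p else hp$mature3p
      if (is.null(m)) next
      feats[[mirna_name(hp$name, arm)]] <-
        list(chrom = hp$chrom, start = m[1L], end = m[2L],
             strand = hp$strand, hairpin = hp$name, arm = arm)
    }
  }
  counts <- matrix(0, nrow = length(feats), ncol = ncol(lib_counts),
                   dimnames = list(names(feats), colnames(lib_counts)))
  ext <- cfg$locus_extension
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    sel <- alignments$chrom == f$chrom & alignments$strand == f$strand &
      alignments$start >= f$start - ext & alignments$end <= f$end + ext
    seqs <- unique(alignments$seq[sel])
    seqs <- seqs[seqs %in% rownames(lib_counts)]
    if (length(seqs) > 0L)
      counts[i, ] <- colSums(lib_counts[seqs, , drop = FALSE])
  }
  rpm <- sweep(counts, 2L, denominators[colnames(counts)], "/") * 1e6
  meta <- data.frame(
    name = names(feats),
    hairpin = vapply(feats, `[[`, character(1L), "hairpin"),
    arm = vapply(feats, `[[`, character(1L), "arm"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(counts = counts, rpm = rpm, features = meta)
}
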