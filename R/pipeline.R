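# End-to-end driver: preprocessing, alignment, annotation, mature counting,
# moRNA calling and statistics over one or more libraries.

#' Build the per-library multiplicity matrix of clean reads
#'
#' @param clean_list named list of clean read data.frames (one per
#'   library).
#' @return numeric matrix, rows = unique read sequences, columns =
#'   libraries.
#' @export
library_count_matrix <- function(clean_list) {
  libs <- names(clean_list)
  if (is.null(libs)) libs <- paste0("lib", seq_along(clean_list))
  uniq <- unique(unlist(lapply(clean_list, function(x) x$seq),
                        use.names = FALSE))
  m <- matrix(0, nrow = length(uniq), ncol = length(clean_list),
              dimnames = list(uniq, libs))
  for (i in seq_along(clean_list)) {
    tab <- table(clean_list[[i]]$seq)
    m[names(tab), i] <- as.numeric(tab)
  }
  m
}

#' Run the full moRNA discovery pipeline
#'
#' Preprocesses each library, aligns the pooled unique sequences to the
#' genome, optionally classifies reads through the ncRNA cascade, counts
#' mature miRNAs with locus extension, collects flank (offset) reads,
#' groups isomoRs, selects each group's most abundant isomoR as reference,
#' quantifies every moRNA per library, and computes arm usage, length
#' distributions and 5'-end consistency.
#'
#' @param libraries named list: per library either a raw read data.frame
#'   (read_id/seq/qual) or a FASTQ path.
#' @param genome genome (named character vector, DNAStringSet or FASTA
#'   path).
#' @param hairpins list of \code{hairpin_record}, or a GFF3 path/text (in
#'   which case it is parsed against \code{genome}).
#' @param adapter 3' adapter sequence.
#' @param cfg a \code{pipeline_config}.
#' @param class_references optional ordered list for
#'   \code{\link{annotate_cascade}}; when NULL the cascade is skipped.
#' @return object of class \code{morna_result}.
#' @export
run_morna_pipeline <- function(libraries, genome, hairpins, adapter,
                               cfg = pipeline_config(),
                               class_references = NULL) {
  genome <- load_genome(genome)
  if (is.character(hairpins))
    hairpins <- parse_hairpin_annotations(hairpins, genome)
  if (is.null(names(libraries)))
    names(libraries) <- paste0("lib", seq_along(libraries))

  pre <- lapply(libraries, preprocess_library, adapter = adapter, cfg = cfg)
  clean <- lapply(pre, `[[`, "reads")
  summaries <- do.call(rbind, lapply(pre, `[[`, "summary"))
  lib_counts <- library_count_matrix(clean)

  aln <- align_reads(rownames(lib_counts), genome, cfg)
  alignments <- aln$alignments
  status <- aln$status
  mapped_seqs <- status$seq[status$status == "aligned"]
  genome_mapped <- colSums(lib_counts[rownames(lib_counts) %in% mapped_seqs,
                                      , drop = FALSE])
  exact_seqs <- unique(alignments$seq[alignments$mismatches == 0L])
  exact_mapped <- colSums(lib_counts[rownames(lib_counts) %in% exact_seqs,
                                     , drop = FALSE])
  denominators <- if (cfg$rpm_denominator == "genome") genome_mapped
                  else exact_mapped

  annotation <- NULL
  if (!is.null(class_references)) {
    labels <- annotate_cascade(rownames(lib_counts), class_references, cfg)
    per_class <- rowsum(lib_counts, labels)
    annotation <- list(labels = stats::setNames(labels,
                                                rownames(lib_counts)),
                       class_counts = per_class)
  }

  ext <- extend_hairpins(hairpins, genome, cfg)
  mature <- count_mature_mirna(alignments, hairpins, lib_counts,
                               denominators, cfg)
  candidates <- collect_offset_reads(alignments, ext, cfg)
  counts_total <- rowSums(lib_counts)
  groups <- group_isoforms(candidates, counts_total)
  calls <- lapply(groups, quantify_morna, alignments = alignments,
                  lib_counts = lib_counts, denominators = denominators,
                  cfg = cfg)
  mstats <- morna_stats(groups, calls, lib_counts, cfg)
  hairpin_mapped <- colSums(
    lib_counts[rownames(lib_counts) %in%
                 unique(alignments$seq[hairpin_overlap(alignments, hairpins)]),
               , drop = FALSE])
  library_stats <- data.frame(
    library = rownames(summaries),
    raw = summaries[, "n_raw"],
    cleaned = summaries[, "n_clean"],
    genome_mapped = genome_mapped[rownames(summaries)],
    hairpin_mapped = hairpin_mapped[rownames(summaries)],
    mor5p = mstats$arm_reads[rownames(summaries), "5p"],
    mor3p = mstats$arm_reads[rownames(summaries), "3p"],
    arm_fraction_5p =
      mstats$arm_fraction_5p[rownames(summaries)],
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(calls = calls, call_table = morna_call_table(calls),
                 groups = groups, candidates = candidates,
                 mature = mature, annotation = annotation,
                 stats = mstats, library_stats = library_stats,
                 preprocess = summaries, alignments = alignments,
                 align_status = status, lib_counts = lib_counts,
                 denominators = denominators,
                 genome_mapped = genome_mapped,
                 exact_mapped = exact_mapped,
                 hairpins = hairpins, config = cfg),
            class = "morna_result")
}

# Rows of the alignment table whose interval overlaps any hairpin locus on
# the same strand (used for the hairpin-mapped library totals).
hairpin_overlap <- function(alignments, hairpins) {
  hit <- rep(FALSE, nrow(alignments))
  for (hp in hairpins) {
    hit <- hit | (alignments$chrom == hp$chrom &
                    alignments$strand == hp$strand &
                    alignments$end > hp$start &
                    alignments$start < hp$end)
  }
  hit
}

#' @export
print.morna_result <- function(x, ...) {
  cat("moRNA discovery result\n")
  cat(sprintf("  libraries: %s\n",
              paste(colnames(x$lib_counts), collapse = ", ")))
  cat(sprintf("  hairpins: %d; moRNA calls: %d (%d moR-5p, %d moR-3p)\n",
              length(x$hairpins), length(x$calls),
              sum(x$call_table$arm == "5p"),
              sum(x$call_table$arm == "3p")))
  cat(sprintf("  mature miRNAs counted: %d\n", nrow(x$mature$counts)))
  invisible(x)
}

#' @export
summary.morna_result <- function(object, ...) {
  x <- object
  cat("moRNA discovery summary\n\n")
  print(x$library_stats, row.names = FALSE)
  cat("\nPooled 5'-arm read fraction:",
      sprintf("%.3f", x$stats$arm_fraction_5p[["pooled"]]), "\n")
  ld <- x$stats$length_dist
  if (length(ld$mor5p) > 0L)
    cat("moR-5p length mode:",
        names(ld$mor5p)[which.max(ld$mor5p)], "nt\n")
  if (length(ld$mor3p) > 0L)
    cat("moR-3p length mode:",
        names(ld$mor3p)[which.max(ld$mor3p)], "nt\n")
  top <- x$call_table
  if (nrow(top) > 0L) {
    tot <- rowSums(top[, grep("^count\\.", names(top)), drop = FALSE])
    top <- top[order(-tot), c("name", "arm", "ref_seq",
                              grep("^rpm\\.", names(top), value = TRUE))]
    cat("\nTop calls by total raw count:\n")
    print(utils::head(top, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Pair mature miRNA and moRNA RPM values by hairpin arm
#'
#' Builds the per-library pairing used by the miR-moR expression
#' correlation: each moRNA call is matched with the mature miRNA annotated
#' on the same (hairpin, arm).
#'
#' @param result a \code{morna_result}.
#' @param library library name (default: first).
#' @return data.frame: hairpin, arm, mir_rpm, mor_rpm.
#' @export
mir_mor_pairs <- function(result, library = colnames(result$lib_counts)[1L]) {
  ct <- result$call_table
  if (nrow(ct) == 0L)
    return(data.frame(hairpin = character(0L), arm = character(0L),
                      mir_rpm = numeric(0L), mor_rpm = numeric(0L)))
  mir <- result$mature
  key <- paste0(mir$features$hairpin, ":", mir$features$arm)
  idx <- match(paste0(ct$hairpin, ":", ct$arm), key)
  data.frame(hairpin = ct$hairpin, arm = ct$arm,
             mir_rpm = ifelse(is.na(idx), NA_real_,
                              mir$rpm[idx, library]),
             mor_rpm = ct[[paste0("rpm.", library)]],
             stringsAsFactors = FALSE)
}

#' Export moRNA calls as BED6 and TSV
#'
#' @param result a \code{morna_result}.
#' @param prefix output path prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}.
#' @return invisibly, the two paths.
#' @export
export_morna_calls <- function(result, prefix) {
  ct <- result$call_table
  bed <- file.path(paste0(prefix, ".bed"))
  tsv <- file.path(paste0(prefix, ".tsv"))
  write_bed6(ct, bed)
  write_tsv(ct, tsv)
  invisible(c(bed = bed, tsv = tsv))
}
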