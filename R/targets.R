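# Seed-match target analysis: 7-mer seed extraction, reverse-complement
# match counting in 3'UTRs, gene-set cross-tabulation, and a
# complementarity-maximizing duplex-site scanner (a deliberately simple
# stand-in for thermodynamic site prediction; its output is a paired-base
# count, not a free energy).

GENE_SETS <- c("down_both", "down_mir_only", "down_mor_only", "other")

#' Extract the 7-mer seed of a small RNA
#'
#' Positions 2-8 (1-based) from the 5' end, after U-to-T normalization.
#'
#' @param small_rna nucleotide string of length at least 8.
#' @param cfg a \code{pipeline_config} (span via \code{cfg$seed_span}).
#' @return the 7-mer seed as a DNA string.
#' @export
seed7 <- function(small_rna, cfg = pipeline_config()) {
  s <- normalize_dna(small_rna)
  if (nchar(s) < cfg$seed_span[2L])
    stop("small RNA shorter than the seed span")
  substr(s, cfg$seed_span[1L], cfg$seed_span[2L])
}

#' Count seed matches in a 3'UTR
#'
#' Number of (overlapping) occurrences of the reverse complement of the
#' seed in the UTR, DNA alphabet.
#'
#' @param utr UTR sequence (may be empty or NA).
#' @param seed a 7-mer seed.
#' @return integer count.
#' @export
count_seed_matches <- function(utr, seed) {
  if (nchar(seed) != 7L) stop("seed must be a 7-mer")
  if (is.na(utr) || nchar(utr) < 7L) return(0L)
  utr <- normalize_dna(utr)
  site <- revcomp(seed)
  Biostrings::countPattern(site, Biostrings::DNAString(utr), fixed = TRUE)
}

#' Cross-tabulate seed matches over gene sets
#'
#' For each gene with an annotated 3'UTR, counts miR and moR seed matches;
#' per gene set, tallies how many genes carry at least one miR match, at
#' least one moR match, and both. Genes lacking a UTR are excluded from all
#' seed counts.
#'
#' @param genes data.frame with columns \code{gene}, \code{utr3} (NA when
#'   unannotated), and \code{set} (one of down_both, down_mir_only,
#'   down_mor_only, other).
#' @param mir_seq,mor_seq the two small RNA sequences.
#' @param cfg a \code{pipeline_config}.
#' @return object of class \code{seed_report}: \code{per_gene} (gene, set,
#'   has_utr, mir_matches, mor_matches) and \code{per_set}
#'   (n_genes, n_genes_with_utr, n_mir_matched, n_mor_matched,
#'   n_both_matched).
#' @export
crosstab_gene_sets <- function(genes, mir_seq, mor_seq,
                               cfg = pipeline_config()) {
  stopifnot(all(c("gene", "utr3", "set") %in% names(genes)))
  bad <- setdiff(unique(genes$set), GENE_SETS)
  if (length(bad) > 0L)
    stop("unknown gene set label(s): ", paste(bad, collapse = ", "))
  mir_seed <- seed7(mir_seq, cfg)
  mor_seed <- seed7(mor_seq, cfg)
  has_utr <- !is.na(genes$utr3) & nchar(genes$utr3) > 0L
  per_gene <- data.frame(
    gene = genes$gene,
    set = factor(genes$set, levels = GENE_SETS),
    has_utr = has_utr,
    mir_matches = NA_integer_,
    mor_matches = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in which(has_utr)) {
    per_gene$mir_matches[i] <- count_seed_matches(genes$utr3[i], mir_seed)
    per_gene$mor_matches[i] <- count_seed_matches(genes$utr3[i], mor_seed)
  }
  per_set <- do.call(rbind, lapply(GENE_SETS, function(s) {
    g <- per_gene[per_gene$set == s, , drop = FALSE]
    gu <- g[g$has_utr, , drop = FALSE]
    data.frame(set = s,
               n_genes = nrow(g),
               n_genes_with_utr = nrow(gu),
               n_mir_matched = sum(gu$mir_matches >= 1L),
               n_mor_matched = sum(gu$mor_matches >= 1L),
               n_both_matched = sum(gu$mir_matches >= 1L &
                                      gu$mor_matches >= 1L),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_gene = per_gene, per_set = per_set,
                 mir_seed = mir_seed, mor_seed = mor_seed),
            class = "seed_report")
}

#' @export
print.seed_report <- function(x, ...) {
  cat(sprintf("Seed report (miR seed %s, moR seed %s)\n",
              x$mir_seed, x$mor_seed))
  print(x$per_set, row.names = FALSE)
  invisible(x)
}

#' Best complementarity site of a small RNA in a 3'UTR
#'
#' Scans every ungapped antiparallel registration of the small RNA against
#' the UTR and reports the site with the maximal paired-base count
#' (Watson-Crick, plus G:U wobble when \code{cfg$wobble_pairs}); ties go to
#' the 5'-most UTR position. This is a complementarity score, not a free
#' energy.
#'
#' @param small_rna small RNA sequence.
#' @param utr UTR sequence, at least as long as the small RNA.
#' @param cfg a \code{pipeline_config}.
#' @return list with \code{position} (1-based UTR offset of the site),
#'   \code{paired} (paired-base count), \code{site_seq}, and
#'   \code{schematic} (3 text lines: UTR site 5'-3', pairing symbols,
#'   small RNA 3'-5').
#' @export
best_duplex_site <- function(small_rna, utr, cfg = pipeline_config()) {
  sr <- normalize_dna(small_rna)
  utr <- normalize_dna(utr)
  L <- nchar(sr)
  n <- nchar(utr)
  if (n < L) stop("UTR shorter than the small RNA")
  a <- strsplit(sr, "", fixed = TRUE)[[1L]]
  u <- strsplit(utr, "", fixed = TRUE)[[1L]]
  # antiparallel: small RNA position k pairs UTR position p + L - k
  paired <- integer(n - L + 1L)
  for (k in seq_len(L)) {
    idx <- seq_len(n - L + 1L) + (L - k)
    paired <- paired + base_pairs_ok(a[k], u[idx], cfg$wobble_pairs)
  }
  p <- which.max(paired)  # which.max returns the first (5'-most) maximum
  site <- substr(utr, p, p + L - 1L)
  sb <- strsplit(site, "", fixed = TRUE)[[1L]]
  arev <- rev(a)
  sym <- vapply(seq_len(L), function(i) {
    if (base_pairs_ok(arev[i], sb[i], wobble = FALSE)) "|"
    else if (cfg$wobble_pairs && base_pairs_ok(arev[i], sb[i], TRUE)) ":"
    else " "
  }, character(1L))
  schematic <- c(paste0("5'-", site, "-3' UTR"),
                 paste0("   ", paste(sym, collapse = ""), "   "),
                 paste0("3'-", paste(arev, collapse = ""), "-5' sRNA"))
  list(position = p, paired = paired[p], site_seq = site,
       schematic = schematic)
}
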