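# File-format I/O. Standard formats go through Biostrings / rtracklayer;
# everything is converted at this boundary to the package's internal
# representations (plain character vectors and 0-based half-open
# data.frames).

#' Load a genome into a named character vector
#'
#' Accepts a named character vector (returned unchanged apart from
#' normalization), a \code{DNAStringSet}, or a FASTA file path.
#'
#' @param genome genome in any of the accepted forms.
#' @return named character vector of uppercase chromosome sequences.
#' @export
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    genome <- out
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  vapply(genome, normalize_dna, character(1L))
}

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  load_genome(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file path.
#' @return data.frame with columns \code{read_id}, \code{seq}, \code{qual}.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with \code{read_id}, \code{seq}, \code{qual}.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a GFF3 file or text into a flat table
#'
#' Coordinates are converted from 1-based inclusive to 0-based half-open.
#'
#' @param gff file path or character vector of GFF3 lines.
#' @return data.frame with columns chrom, start, end, strand, feature_type,
#'   id, name, derives_from.
#' @export
read_gff3 <- function(gff) {
  path <- gff
  if (length(gff) > 1L || grepl("\n", gff[1L], fixed = TRUE) ||
      !file.exists(gff[1L])) {
    path <- tempfile(fileext = ".gff3")
    writeLines(if (length(gff) > 1L) gff else
                 strsplit(gff, "\n", fixed = TRUE)[[1L]], path)
    on.exit(unlink(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (!nm %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[nm]]
    if (is.list(v) || methods::is(v, "CharacterList")) {
      v <- vapply(v, function(e) if (length(e) == 0L) NA_character_
                  else as.character(e[[1L]]), character(1L))
    }
    as.character(v)
  }
  ids <- getcol("ID")
  nms <- getcol("Name")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(mc$type),
    id = ids,
    name = ifelse(is.na(nms), ids, nms),
    derives_from = getcol("Derives_from"),
    stringsAsFactors = FALSE)
}

#' Write hairpin records as miRBase-dialect GFF3
#'
#' @param hairpins list of \code{hairpin_record}.
#' @param path output path.
#' @export
write_hairpin_gff3 <- function(hairpins, path) {
  lines <- c("##gff-version 3")
  for (hp in hairpins) {
    lines <- c(lines, paste(hp$chrom, "moRfinder", "miRNA_primary_transcript",
                            hp$start + 1L, hp$end, ".", hp$strand, ".",
                            sprintf("ID=%s;Name=%s", hp$name, hp$name),
                            sep = "\t"))
    for (arm in c("5p", "3p")) {
      m <- if (arm == "5p") hp$mature5p else hp$mature3p
      if (is.null(m)) next
      mname <- mirna_name(hp$name, arm)
      lines <- c(lines, paste(hp$chrom, "moRfinder", "miRNA",
                              m[1L] + 1L, m[2L], ".", hp$strand, ".",
                              sprintf("ID=%s;Name=%s;Derives_from=%s",
                                      mname, mname, hp$name),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph conservation track
#'
#' @param path bedGraph file path.
#' @return data.frame chrom, start (0-based), end (exclusive), score.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score,
             stringsAsFactors = FALSE)
}

#' Write a conservation track as bedGraph
#'
#' @param track data.frame chrom, start, end, score (0-based half-open).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(paste(track$chrom, track$start, track$end,
                   format(track$score, trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Export intervals as BED6
#'
#' @param df data.frame with chrom, start, end, strand and a \code{name}
#'   column; coordinates 0-based half-open.
#' @param path output path.
#' @param score optional numeric score column values (default 0).
#' @export
write_bed6 <- function(df, path, score = 0) {
  writeLines(paste(df$chrom, df$start, df$end, df$name,
                   rep_len(score, nrow(df)), df$strand, sep = "\t"), path)
  invisible(path)
}

# TSV writers used by the exporters.
write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
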