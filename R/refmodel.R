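#' Construct a hairpin record
#'
#' A miRNA precursor with its genomic locus, sense-strand sequence and
#' optional annotated mature arms. All coordinates are 0-based half-open
#' genome coordinates; GFF3 input/output converts at the boundary.
#'
#' @param name precursor identifier.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open locus.
#' @param strand "+" or "-".
#' @param seq precursor sequence in sense (transcript) orientation.
#' @param mature5p,mature3p optional integer pairs \code{c(start, end)} in
#'   genome coordinates, or NULL.
#' @return object of class \code{hairpin_record}.
#' @export
hairpin_record <- function(name, chrom, start, end, strand, seq,
                           mature5p = NULL, mature3p = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end))
    stop("invalid hairpin locus for ", name)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  seq <- normalize_dna(seq)
  if (nchar(seq) != end - start)
    stop("sequence length does not match locus length for ", name)
  check_mat <- function(m, lab) {
    if (is.null(m)) return(NULL)
    m <- as.integer(m)
    if (length(m) != 2L || m[1L] >= m[2L])
      stop("invalid ", lab, " interval for ", name)
    if (m[1L] < start || m[2L] > end)
      stop(lab, " interval of ", name, " lies outside the precursor")
    m
  }
  mature5p <- check_mat(mature5p, "mature5p")
  mature3p <- check_mat(mature3p, "mature3p")
  if (!is.null(mature5p) && !is.null(mature3p)) {
    # 5p precedes 3p in transcript orientation
    ok <- if (strand == "+") mature5p[2L] <= mature3p[1L]
          else mature3p[2L] <= mature5p[1L]
    if (!ok) stop("mature5p does not precede mature3p on ", name)
  }
  structure(list(name = name, chrom = chrom, start = start, end = end,
                 strand = strand, seq = seq,
                 mature5p = mature5p, mature3p = mature3p),
            class = "hairpin_record")
}

#' @export
print.hairpin_record <- function(x, ...) {
  cat(sprintf("<hairpin %s %s:%d-%d(%s) len=%d 5p=%s 3p=%s>\n",
              x$name, x$chrom, x$start, x$end, x$strand, x$end - x$start,
              if (is.null(x$mature5p)) "-" else paste(x$mature5p, collapse = ".."),
              if (is.null(x$mature3p)) "-" else paste(x$mature3p, collapse = "..")))
  invisible(x)
}

# Transcript-relative offset of a genome position from the precursor 5' end.
transcript_offset <- function(hp, gpos) {
  if (hp$strand == "+") gpos - hp$start else hp$end - gpos
}

#' Extract the mature arm sequence from a hairpin record
#'
#' @param hp a \code{hairpin_record}.
#' @param arm "5p" or "3p".
#' @return the mature sequence in transcript orientation, or NULL when the
#'   arm is not annotated.
#' @export
mature_seq <- function(hp, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  m <- if (arm == "5p") hp$mature5p else hp$mature3p
  if (is.null(m)) return(NULL)
  if (hp$strand == "+") {
    substr(hp$seq, m[1L] - hp$start + 1L, m[2L] - hp$start)
  } else {
    substr(hp$seq, hp$end - m[2L] + 1L, hp$end - m[1L])
  }
}

#' Parse miRBase-style hairpin annotations
#'
#' Reads a miRBase-dialect GFF3 (\code{miRNA_primary_transcript} features
#' plus \code{miRNA} features linked by \code{Derives_from}) and extracts
#' precursor sequences from the genome, reverse-complementing minus-strand
#' records into sense orientation. Mature arms are assigned 5p/3p by their
#' precursor-relative position.
#'
#' @param gff path to a GFF3 file, or a character vector of GFF3 text lines.
#' @param genome named character vector of chromosome sequences, a
#'   \code{DNAStringSet}, or a FASTA path.
#' @return list of \code{hairpin_record}.
#' @export
parse_hairpin_annotations <- function(gff, genome) {
  genome <- load_genome(genome)
  gr <- read_gff3(gff)
  prim <- gr[gr$feature_type == "miRNA_primary_transcript", , drop = FALSE]
  mat  <- gr[gr$feature_type == "miRNA", , drop = FALSE]
  if (nrow(prim) == 0L) stop("no miRNA_primary_transcript features found")
  recs <- vector("list", nrow(prim))
  names(recs) <- prim$name
  for (i in seq_len(nrow(prim))) {
    p <- prim[i, ]
    if (!p$chrom %in% names(genome))
      stop("chromosome ", p$chrom, " not present in genome")
    chrom_seq <- genome[[p$chrom]]
    if (p$end > nchar(chrom_seq))
      stop("precursor ", p$name, " extends beyond chromosome ", p$chrom)
    s <- substr(chrom_seq, p$start + 1L, p$end)
    if (p$strand == "-") s <- revcomp(s)
    matching <- mat[!is.na(mat$derives_from) & mat$derives_from == p$id, ,
                    drop = FALSE]
    m5 <- m3 <- NULL
    if (nrow(matching) > 0L) {
      offs <- vapply(seq_len(nrow(matching)), function(j) {
        m <- matching[j, ]
        if (m$start < p$start || m$end > p$end)
          stop("mature ", m$name, " lies outside its precursor ", p$name)
        if (p$strand == "+") m$start - p$start else p$end - m$end
      }, numeric(1L))
      ord <- order(offs)
      matching <- matching[ord, , drop = FALSE]
      if (nrow(matching) > 2L)
        stop("precursor ", p$name, " has more than two mature features")
      if (nrow(matching) == 2L) {
        m5 <- c(matching$start[1L], matching$end[1L])
        m3 <- c(matching$start[2L], matching$end[2L])
      } else {
        # single-arm annotation: assign by which precursor half holds the
        # mature midpoint (transcript orientation)
        m <- c(matching$start[1L], matching$end[1L])
        mid <- transcript_offset(
          list(strand = p$strand, start = p$start, end = p$end),
          mean(m))
        if (mid <= (p$end - p$start) / 2) m5 <- m else m3 <- m
      }
    }
    recs[[i]] <- hairpin_record(p$name, p$chrom, p$start, p$end, p$strand,
                                s, mature5p = m5, mature3p = m3)
  }
  orphans <- mat$name[!is.na(mat$derives_from) &
                        !(mat$derives_from %in% prim$id)]
  if (length(orphans) > 0L)
    stop("mature feature(s) without a matching precursor: ",
         paste(orphans, collapse = ", "))
  if (any(is.na(mat$derives_from)))
    stop("mature feature(s) lacking a Derives_from attribute: ",
         paste(mat$name[is.na(mat$derives_from)], collapse = ", "))
  recs
}

#' Build an extended hairpin with its five-region map
#'
#' Widens a precursor locus by \code{cfg$flank} nt on each side (truncated
#' at chromosome bounds) and partitions the extended locus into the regions
#' moR-5p / miR-5p / loop / miR-3p / moR-3p. The moR regions are exactly the
#' flanks, measured from the precursor boundary; mir regions equal the
#' annotated mature loci; the loop label covers the residual interior (which
#' may be split into several segments when matures do not abut the
#' precursor ends). On the minus strand the moR-5p region lies at the higher
#' genome coordinates.
#'
#' @param hp a \code{hairpin_record}.
#' @param cfg a \code{pipeline_config}.
#' @param chrom_len length of the chromosome carrying the hairpin.
#' @return object of class \code{extended_hairpin} with elements
#'   \code{hairpin}, \code{flank}, \code{ext_start}, \code{ext_end},
#'   \code{regions} (data.frame label/start/end), and clipping flags.
#' @export
build_extended_hairpin <- function(hp, cfg = pipeline_config(), chrom_len) {
  chrom_len <- as.integer(chrom_len)
  if (hp$end > chrom_len) stop("hairpin extends beyond chromosome")
  ext_start <- max(0L, hp$start - cfg$flank)
  ext_end <- min(chrom_len, hp$end + cfg$flank)
  clipped_left <- ext_start > hp$start - cfg$flank
  clipped_right <- ext_end < hp$end + cfg$flank
  left_lab  <- if (hp$strand == "+") "moR5p" else "moR3p"
  right_lab <- if (hp$strand == "+") "moR3p" else "moR5p"
  mir_left  <- if (hp$strand == "+") "mir5p" else "mir3p"
  mir_right <- if (hp$strand == "+") "mir3p" else "mir5p"

  rows <- list()
  add <- function(label, s, e) {
    if (e > s) rows[[length(rows) + 1L]] <<- data.frame(
      label = label, start = s, end = e, stringsAsFactors = FALSE)
  }
  add(left_lab, ext_start, hp$start)
  # interior: order matures by genome coordinate
  mats <- list()
  if (!is.null(hp$mature5p))
    mats[[length(mats) + 1L]] <- list(lab = "mir5p", iv = hp$mature5p)
  if (!is.null(hp$mature3p))
    mats[[length(mats) + 1L]] <- list(lab = "mir3p", iv = hp$mature3p)
  if (length(mats) == 2L && mats[[1L]]$iv[1L] > mats[[2L]]$iv[1L])
    mats <- mats[c(2L, 1L)]
  pos <- hp$start
  for (m in mats) {
    add("loop", pos, m$iv[1L])
    add(m$lab, m$iv[1L], m$iv[2L])
    pos <- m$iv[2L]
  }
  add("loop", pos, hp$end)
  add(right_lab, hp$end, ext_end)
  regions <- do.call(rbind, rows)
  rownames(regions) <- NULL
  structure(list(hairpin = hp, flank = cfg$flank,
                 ext_start = ext_start, ext_end = ext_end,
                 regions = regions,
                 clipped_left = clipped_left, clipped_right = clipped_right),
            class = "extended_hairpin")
}

#' @export
print.extended_hairpin <- function(x, ...) {
  cat(sprintf("<extended hairpin %s %s:%d-%d(%s)>\n", x$hairpin$name,
              x$hairpin$chrom, x$ext_start, x$ext_end, x$hairpin$strand))
  print(x$regions)
  invisible(x)
}

# Genome interval of a named region (possibly multiple rows for "loop");
# returns a data.frame subset of the region map.
region_interval <- function(eh, label) {
  eh$regions[eh$regions$label == label, , drop = FALSE]
}

#' Region lengths of an extended hairpin
#'
#' @param eh an \code{extended_hairpin}.
#' @return named integer vector of total lengths per region label.
#' @export
region_lengths <- function(eh) {
  tapply(eh$regions$end - eh$regions$start, eh$regions$label, sum)
}

#' Build extended hairpins for a reference set
#'
#' @param hairpins list of \code{hairpin_record}.
#' @param genome named character vector (used for chromosome lengths).
#' @param cfg a \code{pipeline_config}.
#' @return named list of \code{extended_hairpin}.
#' @export
extend_hairpins <- function(hairpins, genome, cfg = pipeline_config()) {
  genome <- load_genome(genome)
  out <- lapply(hairpins, function(hp) {
    build_extended_hairpin(hp, cfg, nchar(genome[[hp$chrom]]))
  })
  names(out) <- vapply(hairpins, `[[`, character(1L), "name")
  out
}
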