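# Independent oracles and fixture builders. Everything here is written as
# a separate, deliberately naive implementation so it can stand against
# the package's optimized code paths.

DNA <- c("A", "C", "G", "T")

rnd_dna <- function(len) paste(sample(DNA, len, replace = TRUE),
                               collapse = "")

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# all-offsets brute-force Hamming scan, both strands; N mismatches
# everything. Returns the same columns as align_reads()$alignments.
brute_align <- function(seqs, genome, max_mm, max_loci = Inf) {
  rows <- list()
  status <- character(length(seqs))
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    L <- nchar(s)
    hits <- list()
    for (chrom in names(genome)) {
      g <- genome[[chrom]]
      n <- nchar(g)
      if (n < L) next
      for (strand in c("+", "-")) {
        q <- if (strand == "+") s else rc_chr(s)
        qb <- strsplit(q, "", fixed = TRUE)[[1L]]
        for (off in 0:(n - L)) {
          wb <- strsplit(substr(g, off + 1L, off + L), "",
                         fixed = TRUE)[[1L]]
          mm <- sum(qb != wb | qb == "N" | wb == "N")
          if (mm <= max_mm)
            hits[[length(hits) + 1L]] <- data.frame(
              seq = s, chrom = chrom, start = off, end = off + L,
              strand = strand, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
    k <- length(hits)
    if (k == 0L) status[si] <- "unaligned"
    else if (k > max_loci) status[si] <- "multimapper_overflow"
    else {
      status[si] <- "aligned"
      rows <- c(rows, hits)
    }
  }
  list(alignments = if (length(rows) > 0L) do.call(rbind, rows) else NULL,
       status = status)
}

# canonical sort for alignment-set comparison
sort_aln <- function(df) {
  df <- df[order(df$seq, df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force duplex registration scan, independent of duplex_pair_count
brute_duplex <- function(candidate, mature, window, wobble = TRUE) {
  pairs_tab <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
  if (!wobble) pairs_tab <- list(A = "T", C = "G", G = "C", T = "A")
  a <- strsplit(substr(candidate, 1L, window), "", fixed = TRUE)[[1L]]
  b <- strsplit(mature, "", fixed = TRUE)[[1L]]
  la <- length(a); lb <- length(b)
  best <- 0L
  # candidate position i pairs mature position j, antiparallel: as i
  # increases (5'->3' on the candidate), j decreases on the mature
  for (d in (2L):(la + lb)) {           # i + j == d
    cnt <- 0L
    for (i in seq_len(la)) {
      j <- d - i
      if (j < 1L || j > lb) next
      if (b[j] %in% pairs_tab[[a[i]]]) cnt <- cnt + 1L
    }
    if (cnt > best) best <- cnt
  }
  best
}

# sliding-window overlapping seed-site count
brute_seed_count <- function(utr, seed) {
  site <- rc_chr(seed)
  n <- nchar(utr)
  if (n < 7L) return(0L)
  sum(vapply(1:(n - 6L), function(p) substr(utr, p, p + 6L) == site,
             logical(1L)))
}

rank_pearson <- function(x, y) stats::cor(rank(x), rank(y))

# quality string helpers: Q38 ('G') good, Q8 (')') bad
q_good <- function(n) strrep("G", n)
q_bad <- function(n) strrep(")", n)

read_df <- function(seqs, quals = q_good(nchar(seqs)),
                    ids = sprintf("r%04d", seq_along(seqs))) {
  data.frame(read_id = ids, seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

# substitute a base at 1-based position pos so it differs from the original
mutate_at <- function(seq, pos) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) b[p] <- sample(setdiff(DNA, b[p]), 1L)
  paste(b, collapse = "")
}

# a small deterministic single-hairpin world: plus-strand precursor of
# length hp_len at position hp_start, matures at both precursor ends
toy_world <- function(seed = 1L, hp_start = 200L, hp_len = 80L,
                      glen = 600L, strand = "+", mature_len = 22L) {
  set.seed(seed)
  g <- rnd_dna(glen)
  s <- hp_start; e <- hp_start + hp_len
  hp_seq <- substr(g, s + 1L, e)
  if (strand == "-") hp_seq <- rc_chr(hp_seq)
  m5 <- if (strand == "+") c(s, s + mature_len) else c(e - mature_len, e)
  m3 <- if (strand == "+") c(e - mature_len, e) else c(s, s + mature_len)
  hp <- hairpin_record("toy-mir-001", "chrT", s, e, strand, hp_seq,
                       mature5p = m5, mature3p = m3)
  list(genome = c(chrT = g), hp = hp)
}

# genome substring as a read, sense orientation of the given strand
read_at <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") rc_chr(s) else s
}

# mirror a hairpin record onto the reverse-complemented genome
flip_hairpin <- function(hp, glen) {
  flip_iv <- function(iv) if (is.null(iv)) NULL else
    c(glen - iv[2L], glen - iv[1L])
  hairpin_record(hp$name, hp$chrom, glen - hp$end, glen - hp$start,
                 if (hp$strand == "+") "-" else "+", hp$seq,
                 mature5p = flip_iv(hp$mature5p),
                 mature3p = flip_iv(hp$mature3p))
}

# vectorized all-offsets Hamming scan (same contract as brute_align but
# fast enough for genome-scale oracle comparisons): per read and strand,
# accumulates mismatch counts across offsets one read-position at a time.
fast_brute_align <- function(seqs, genome, max_mm, max_loci = Inf) {
  gsplit <- lapply(genome, function(g) strsplit(g, "", fixed = TRUE)[[1L]])
  rows <- list()
  status <- character(length(seqs))
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    L <- nchar(s)
    hits <- list()
    for (chrom in names(genome)) {
      gb <- gsplit[[chrom]]
      n <- length(gb)
      if (n < L) next
      n_off <- n - L + 1L
      for (strand in c("+", "-")) {
        q <- if (strand == "+") s else rc_chr(s)
        qb <- strsplit(q, "", fixed = TRUE)[[1L]]
        mm <- integer(n_off)
        for (k in seq_len(L)) {
          gk <- gb[k:(k + n_off - 1L)]
          mm <- mm + (gk != qb[k] | gk == "N" | qb[k] == "N")
        }
        off <- which(mm <= max_mm)
        if (length(off) > 0L)
          hits[[length(hits) + 1L]] <- data.frame(
            seq = s, chrom = chrom, start = off - 1L, end = off - 1L + L,
            strand = strand, mismatches = mm[off],
            stringsAsFactors = FALSE)
      }
    }
    h <- if (length(hits) > 0L) do.call(rbind, hits) else NULL
    k <- if (is.null(h)) 0L else nrow(h)
    if (k == 0L) status[si] <- "unaligned"
    else if (k > max_loci) status[si] <- "multimapper_overflow"
    else {
      status[si] <- "aligned"
      rows[[length(rows) + 1L]] <- h
    }
  }
  list(alignments = if (length(rows) > 0L) do.call(rbind, rows) else NULL,
       status = status)
}

# degrade a perfect-duplex candidate one paired base at a time until the
# brute-force registration scan reports exactly `target` pairs
candidate_with_pairs <- function(mature, target, window = 20L) {
  cand <- rc_chr(mature)
  cur <- brute_duplex(cand, mature, window)
  while (cur > target) {
    done <- FALSE
    b <- strsplit(cand, "", fixed = TRUE)[[1L]]
    for (i in seq_len(min(window, length(b)))) {
      for (repl in DNA) {
        if (repl == b[i]) next
        b2 <- b; b2[i] <- repl
        c2 <- paste(b2, collapse = "")
        if (brute_duplex(c2, mature, window) == cur - 1L) {
          cand <- c2; cur <- cur - 1L; done <- TRUE; break
        }
      }
      if (done) break
    }
    if (!done) stop("could not degrade duplex further")
  }
  stopifnot(brute_duplex(cand, mature, window) == target)
  cand
}
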