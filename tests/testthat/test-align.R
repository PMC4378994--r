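# Alignment engine vs the brute-force Hamming oracle, the annotation
# cascade, and mature miRNA counting with locus extension.

test_that("unique reads align once; distant reads do not align", {
  set.seed(31)
  g <- c(chrA = rnd_dna(2000))
  cfg <- pipeline_config()
  r <- substr(g[["chrA"]], 501, 522)
  out <- align_reads(r, g, cfg)
  expect_identical(nrow(out$alignments), 1L)
  expect_identical(out$alignments$start, 500L)
  expect_identical(out$alignments$mismatches, 0L)
  # every window at Hamming distance >= 3 -> unaligned; use a read of
  # impossible composition for this genome size
  bad <- strrep("N", 22)
  out2 <- align_reads(bad, g, cfg)
  expect_identical(out2$status$status, "unaligned")
})

test_that("alignment equals the all-offsets Hamming scan", {
  set.seed(32)
  g <- c(chrA = rnd_dna(2500), chrB = rnd_dna(800))
  cfg <- pipeline_config()
  # mixture: planted exact/mutated/reverse-complement reads + random reads
  reads <- character(0L)
  for (i in 1:25) {
    p <- sample(2300, 1L)
    L <- sample(16:26, 1L)
    r <- substr(g[["chrA"]], p, p + L - 1L)
    if (i %% 3L == 0L) r <- mutate_at(r, sample(L, sample(1:3, 1L)))
    if (i %% 4L == 0L) r <- rc_chr(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, vapply(1:15, function(i) rnd_dna(20), character(1L)))
  got <- align_reads(reads, g, cfg)
  want <- brute_align(unique(reads), g, cfg$max_mismatches, cfg$max_loci)
  expect_equal(sort_aln(got$alignments), sort_aln(want$alignments))
  expect_identical(got$status$status,
                   want$status[match(got$status$seq, unique(reads))])
})

test_that("reads with too many placements are flagged as multimappers", {
  set.seed(33)
  core <- rnd_dna(18)
  g <- c(chrA = paste0(rnd_dna(50),
                       paste(rep(paste0(core, rnd_dna(10)), 11L),
                             collapse = ""),
                       rnd_dna(50)))
  out <- align_reads(core, g, pipeline_config())
  expect_identical(out$status$status, "multimapper_overflow")
  expect_identical(nrow(out$alignments), 0L)
  # within the cap the same read reports every origin
  out2 <- align_reads(core, g, pipeline_config(max_loci = 12))
  expect_identical(nrow(out2$alignments), 11L)
})

test_that("lowering the mismatch tolerance never gains alignments", {
  set.seed(34)
  g <- c(chrA = rnd_dna(3000))
  reads <- vapply(1:30, function(i) {
    p <- sample(2900, 1L)
    mutate_at(substr(g[["chrA"]], p, p + 19L), sample(20L, sample(0:3, 1L)))
  }, character(1L))
  n_prev <- Inf
  for (mm in c(3L, 2L, 1L, 0L)) {
    out <- align_reads(reads, g, pipeline_config(max_mismatches = mm))
    n_aligned <- sum(out$status$status == "aligned")
    expect_lte(n_aligned, n_prev)
    n_prev <- n_aligned
  }
})

test_that("strand involution reproduces placements with strands flipped", {
  set.seed(35)
  g <- c(chrA = rnd_dna(1500))
  gflip <- c(chrA = rc_chr(g[["chrA"]]))
  reads <- vapply(1:12, function(i) {
    p <- sample(1400, 1L)
    r <- substr(g[["chrA"]], p, p + 20L)
    if (i %% 2L) r else rc_chr(r)
  }, character(1L))
  cfg <- pipeline_config()
  a <- sort_aln(align_reads(reads, g, cfg)$alignments)
  b <- align_reads(reads, gflip, cfg)$alignments
  glen <- nchar(g[["chrA"]])
  b$new_start <- glen - b$end
  b$end <- glen - b$start
  b$start <- b$new_start
  b$strand <- ifelse(b$strand == "+", "-", "+")
  b <- sort_aln(b[, colnames(a)])
  expect_equal(a, b)
})

test_that("annotation cascade is first-match-wins in the stated order", {
  set.seed(36)
  hp <- rnd_dna(80)
  trna <- rnd_dna(75)
  pirna <- rnd_dna(30)
  refs <- list(mirna_hairpin = hp, piRNA = pirna, tRNA = trna)
  cfg <- pipeline_config()
  # read matching both the hairpin (1 mismatch) and a tRNA exactly: take
  # a tRNA substring and plant a 1-mismatch copy inside the hairpin
  r_trna <- substr(trna, 10, 29)
  hp2 <- paste0(substr(hp, 1, 20), mutate_at(r_trna, 7L), substr(hp, 41, 80))
  labels <- annotate_cascade(r_trna, list(mirna_hairpin = hp2, tRNA = trna),
                             cfg)
  expect_identical(as.character(labels), "mirna_hairpin")
  # read matching only the piRNA set exactly
  expect_identical(
    as.character(annotate_cascade(substr(pirna, 3, 24), refs, cfg)),
    "piRNA")
  expect_error(annotate_cascade("ACGT", list(junk = "ACGT"), cfg),
               "unknown class label")
})

test_that("cascade labels agree with a naive per-read evaluation", {
  set.seed(37)
  refs <- list(mirna_hairpin = vapply(1:3, function(i) rnd_dna(80),
                                      character(1L)),
               snoRNA = vapply(1:2, function(i) rnd_dna(120), character(1L)),
               rRNA = rnd_dna(200),
               tRNA = vapply(1:2, function(i) rnd_dna(72), character(1L)))
  cfg <- pipeline_config()
  reads <- character(0L)
  for (i in 1:50) {
    src <- sample(c(names(refs), "random"), 1L)
    r <- if (src == "random") rnd_dna(sample(18:24, 1L)) else {
      ref <- sample(refs[[src]], 1L)
      p <- sample(nchar(ref) - 21L, 1L)
      w <- substr(ref, p, p + 20L)
      if (src == "mirna_hairpin" && stats::runif(1L) < 0.5)
        mutate_at(w, sample(21L, sample(1:2, 1L))) else w
    }
    reads <- c(reads, r)
  }
  got <- annotate_cascade(reads, refs, cfg)
  # oracle: literal cascade over individual references
  contains_mm <- function(read, ref, mm_max) {
    L <- nchar(read)
    if (nchar(ref) < L) return(FALSE)
    rb <- strsplit(read, "")[[1L]]
    for (p in 0:(nchar(ref) - L)) {
      wb <- strsplit(substr(ref, p + 1L, p + L), "")[[1L]]
      if (sum(rb != wb) <= mm_max) return(TRUE)
    }
    FALSE
  }
  want <- vapply(reads, function(r) {
    for (lab in names(refs)) {
      mm <- if (lab == "mirna_hairpin") 2L else 0L
      if (any(vapply(refs[[lab]], function(ref) contains_mm(r, ref, mm),
                     logical(1L))))
        return(lab)
    }
    "unannotated"
  }, character(1L), USE.NAMES = FALSE)
  expect_identical(as.character(got), want)
  # exhaustiveness: exactly one label per read
  expect_false(anyNA(got))
})

test_that("mature counting honors the two-nucleotide locus extension", {
  w <- toy_world(seed = 38)
  cfg <- pipeline_config()
  hp <- w$hp
  m5 <- hp$mature5p
  g <- w$genome
  reads <- c(exact = read_at(g, "chrT", m5[1L], m5[2L]),
             within = read_at(g, "chrT", m5[1L] - 2L, m5[2L] + 1L),
             outside = read_at(g, "chrT", m5[1L] - 3L, m5[2L]))
  aln <- align_reads(reads, g, cfg)$alignments
  lc <- matrix(1, nrow = 3L, ncol = 1L,
               dimnames = list(unname(reads), "lib1"))
  res <- count_mature_mirna(aln, list(hp), lc, c(lib1 = 3), cfg)
  expect_equal(res$counts["toy-miR-001-5p", "lib1"], 2)
  expect_equal(res$rpm["toy-miR-001-5p", "lib1"], 2 / 3 * 1e6)
})

test_that("paralogous loci sharing one sequence receive identical counts", {
  set.seed(39)
  hp_seq <- rnd_dna(80)
  spacer <- rnd_dna(150)
  g <- c(chrP = paste0(rnd_dna(100), hp_seq, spacer, hp_seq, rnd_dna(100)))
  s1 <- 100L; s2 <- 100L + 80L + 150L
  mk <- function(name, s) hairpin_record(name, "chrP", s, s + 80L, "+",
                                         hp_seq,
                                         mature5p = c(s, s + 22L),
                                         mature3p = c(s + 58L, s + 80L))
  hps <- list(mk("par-mir-1", s1), mk("par-mir-2", s2))
  reads <- substr(hp_seq, 1, 22)
  aln <- align_reads(reads, g, pipeline_config())$alignments
  lc <- matrix(5, 1L, 1L, dimnames = list(reads, "lib1"))
  res <- count_mature_mirna(aln, hps, lc, c(lib1 = 5), pipeline_config())
  expect_equal(unname(res$counts["par-miR-1-5p", 1L]),
               unname(res$counts["par-miR-2-5p", 1L]))
  expect_equal(unname(res$counts["par-miR-1-5p", 1L]), 5)
})
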