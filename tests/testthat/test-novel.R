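# Minor-arm miRNA calling, novel-hairpin post-filters, duplex pairing and
# conservation classification.

test_that("duplex pairing matches the exhaustive registration scan", {
  cfg <- pipeline_config()
  set.seed(51)
  m <- rnd_dna(22)
  # perfect duplex: the reverse complement of the mature's first 20 nt
  perfect <- rc_chr(substr(m, 1, 20))
  expect_identical(duplex_pair_count(perfect, substr(m, 1, 20), cfg), 20L)
  # no complementarity at all
  expect_identical(duplex_pair_count(strrep("A", 20), strrep("A", 20), cfg),
                   0L)
  # randomized pairs, with and without wobble
  for (i in 1:25) {
    cand <- rnd_dna(sample(18:24, 1L))
    mat <- rnd_dna(sample(18:24, 1L))
    expect_identical(duplex_pair_count(cand, mat, cfg),
                     brute_duplex(cand, mat, 20L, wobble = TRUE))
    cfg_nw <- pipeline_config(wobble_pairs = FALSE)
    expect_identical(duplex_pair_count(cand, mat, cfg_nw),
                     brute_duplex(cand, mat, 20L, wobble = FALSE))
  }
})

test_that("duplex pairing is symmetric and monotone in the window", {
  cfg <- pipeline_config()
  set.seed(52)
  for (i in 1:10) {
    a <- rnd_dna(18); b <- rnd_dna(20)
    expect_identical(duplex_pair_count(a, b, cfg, window = 25L),
                     duplex_pair_count(b, a, cfg, window = 25L))
    w <- vapply(c(8L, 12L, 16L, 20L), function(win) {
      duplex_pair_count(a, b, cfg, window = win)
    }, integer(1L))
    expect_true(all(diff(w) >= 0L))
  }
})

# single-arm hairpin whose opposite arm carries a planted candidate read
minor_arm_world <- function(seed, planted_rc = TRUE) {
  set.seed(seed)
  g <- rnd_dna(400)
  s <- 150L; e <- 230L
  hp_seq0 <- substr(g, s + 1L, e)
  mature <- substr(hp_seq0, 1, 22)
  cand <- if (planted_rc) rc_chr(mature) else rnd_dna(22)
  # plant the candidate on the 3' arm of the precursor
  hp_seq <- paste0(substr(hp_seq0, 1, 54), cand, substr(hp_seq0, 77, 80))
  g <- paste0(substr(g, 1, s), hp_seq, substr(g, e + 1, 400))
  hp <- hairpin_record("nv-mir-1", "chrN", s, e, "+", hp_seq,
                       mature5p = c(s, s + 22L))
  list(genome = c(chrN = g), hp = hp, cand = cand, mature = mature)
}

test_that("minor-arm calls apply the three acceptance criteria", {
  cfg <- pipeline_config()
  w <- minor_arm_world(53, planted_rc = TRUE)
  a <- data.frame(seq = w$cand, chrom = "chrN", start = 150L + 54L,
                  end = 150L + 76L, strand = "+", mismatches = 0L,
                  stringsAsFactors = FALSE)
  # 12 perfect reads with strong pairing -> accepted
  out <- call_minor_arm(w$hp, a, stats::setNames(12, w$cand), cfg)
  expect_identical(out$candidate_seq, w$cand)
  expect_identical(out$arm, "3p")
  expect_gte(out$pair_count, 14L)
  expect_true(out$accepted)
  # 9 reads, otherwise perfect -> rejected on support
  out9 <- call_minor_arm(w$hp, a, stats::setNames(9, w$cand), cfg)
  expect_false(out9$accepted)
  # weak pairing -> rejected even with support
  w2 <- minor_arm_world(54, planted_rc = FALSE)
  a2 <- data.frame(seq = w2$cand, chrom = "chrN", start = 150L + 54L,
                   end = 150L + 76L, strand = "+", mismatches = 0L,
                   stringsAsFactors = FALSE)
  out2 <- call_minor_arm(w2$hp, a2, stats::setNames(30, w2$cand), cfg)
  expect_lt(out2$pair_count, 14L)
  expect_false(out2$accepted)
  # two-arm hairpin is skipped with a log message
  both <- toy_world(seed = 55)$hp
  expect_message(res <- call_minor_arm(both, a, stats::setNames(12, w$cand),
                                       cfg),
                 "exactly one")
  expect_null(res)
})

test_that("a planted minor-arm product is recovered through the aligner", {
  cfg <- pipeline_config()
  w <- minor_arm_world(56, planted_rc = TRUE)
  reads <- c(rep(w$cand, 15L), rep(substr(w$hp$seq, 2, 21), 40L))
  aln <- align_reads(unique(reads), w$genome, cfg)$alignments
  counts <- stats::setNames(as.numeric(table(reads)[unique(reads)]),
                            unique(reads))
  out <- call_minor_arm(w$hp, aln, counts, cfg)
  expect_identical(out$candidate_seq, w$cand)
  expect_true(out$accepted)
})

test_that("novel hairpin filters reject extreme GC and high copy number", {
  cfg <- pipeline_config()
  set.seed(57)
  stack <- data.frame(seq = character(0L), count = numeric(0L))
  # GC fraction 0.10 fails the composition criterion
  at_rich <- paste0(strrep("AT", 35), "GCGCGCA")  # 77 nt, GC = 6/77
  g <- c(chrA = paste0(rnd_dna(60), at_rich, rnd_dna(60)))
  rep_at <- filter_novel_hairpin("cand-at", at_rich, stack, g, cfg)
  expect_lt(rep_at$gc_fraction, 0.15)
  expect_false(rep_at$passed)
  # hairpin embedded 12 times fails the copy criterion
  core <- rnd_dna(70)
  g12 <- c(chrA = paste0(rnd_dna(30),
                         paste(replicate(12L, paste0(core, rnd_dna(15))),
                               collapse = ""), rnd_dna(30)))
  stack_ok <- data.frame(seq = substr(core, 5, 26), count = 50,
                         stringsAsFactors = FALSE)
  rep12 <- filter_novel_hairpin("cand-12x", core, stack_ok, g12, cfg)
  expect_gte(rep12$genomic_copies, 12L)
  expect_false(rep12$passed)
  # read support below 10 exact reads fails
  g1 <- c(chrA = paste0(rnd_dna(50), core, rnd_dna(50)))
  stack9 <- data.frame(seq = substr(core, 5, 26), count = 9,
                       stringsAsFactors = FALSE)
  expect_false(filter_novel_hairpin("cand-9r", core, stack9, g1,
                                    cfg)$passed)
  stack10 <- data.frame(seq = substr(core, 5, 26), count = 10,
                        stringsAsFactors = FALSE)
  expect_true(filter_novel_hairpin("cand-10r", core, stack10, g1,
                                   cfg)$passed)
})

test_that("the GC criterion reproduces a character-count oracle", {
  # a published novel-hairpin sequence; GC counted by hand: 30 G+C over
  # 63 nt
  hp <- "AGAAGAATTGGCCTACTCAGGtgtcagcaaagccttcctctcTGAATAGGTCAATTCCCCTCA"
  expect_equal(gc_fraction(hp), 30 / 63)
  cfg <- pipeline_config()
  g <- c(chr5 = paste0(rnd_dna(40), toupper(hp), rnd_dna(40)))
  stack <- data.frame(seq = toupper(substr(hp, 1, 21)), count = 14,
                      stringsAsFactors = FALSE)
  rep <- filter_novel_hairpin("hsa-cand-1", hp, stack, g, cfg)
  expect_equal(rep$gc_fraction, 30 / 63)
  expect_true(rep$gc_fraction >= 0.15 && rep$gc_fraction <= 0.90)
  expect_true(rep$passed)
})

test_that("acceptance flags are pure functions of the three quantities", {
  cfg <- pipeline_config()
  set.seed(58)
  core <- rnd_dna(70)
  g1 <- c(chrA = paste0(rnd_dna(50), core, rnd_dna(50)))
  for (reads in c(9, 10, 11)) {
    stack <- data.frame(seq = substr(core, 3, 24), count = reads,
                        stringsAsFactors = FALSE)
    rep <- filter_novel_hairpin("x", core, stack, g1, cfg)
    expect_identical(rep$passed,
                     rep$main_product_reads >= 10 &&
                       rep$genomic_copies <= 10 &&
                       rep$gc_fraction >= 0.15 && rep$gc_fraction <= 0.90)
  }
})

test_that("conservation calls use a strict mean threshold", {
  cfg <- pipeline_config()
  iv <- list(chrom = "c1", start = 100L, end = 160L)
  flat <- function(score) data.frame(chrom = "c1", start = 0L, end = 500L,
                                     score = score)
  expect_true(conservation_class(iv, flat(0.8), cfg)$conserved)
  expect_equal(conservation_class(iv, flat(0.8), cfg)$mean_score, 0.8)
  # boundary: mean exactly 0.5 is NOT conserved
  expect_false(conservation_class(iv, flat(0.5), cfg)$conserved)
  # mixed track equals the direct average
  track <- data.frame(chrom = "c1", start = c(100L, 130L),
                      end = c(130L, 160L), score = c(0.9, 0.2))
  cc <- conservation_class(iv, track, cfg)
  expect_equal(cc$mean_score, (30 * 0.9 + 30 * 0.2) / 60)
  # uncovered positions score zero and are reported
  half <- data.frame(chrom = "c1", start = 100L, end = 130L, score = 1.0)
  cc2 <- conservation_class(iv, half, cfg)
  expect_equal(cc2$mean_score, 0.5)
  expect_identical(cc2$n_missing, 30L)
  expect_error(conservation_class(list(chrom = "c1", start = 5L, end = 5L),
                                  flat(1), cfg), "empty interval")
})
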