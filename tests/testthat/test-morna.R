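# Offset-read collection, isomoR grouping, reference-locus quantification,
# 5'-end consistency, statistics and the export filter.

# build a one-hairpin world plus alignments for a set of intervals
flank_setup <- function(seed = 41, strand = "+") {
  w <- toy_world(seed = seed, strand = strand)
  eh <- extend_hairpins(list(w$hp), w$genome)[[1L]]
  list(w = w, eh = eh)
}

aln_at <- function(g, chrom, start, end, strand, mismatches = 0L) {
  data.frame(seq = read_at(g, chrom, start, end, strand), chrom = chrom,
             start = start, end = end, strand = strand,
             mismatches = mismatches, stringsAsFactors = FALSE)
}

test_that("offset-read collection applies the containment and strand rules", {
  fs <- flank_setup()
  hp <- fs$w$hp; g <- fs$w$genome
  cfg <- pipeline_config()
  a <- rbind(
    aln_at(g, "chrT", hp$start - 25L, hp$start - 5L, "+"),   # in 5' flank
    aln_at(g, "chrT", hp$start + 5L, hp$start + 25L, "+"),   # inside hairpin
    aln_at(g, "chrT", hp$start - 25L, hp$start - 5L, "-"),   # antisense
    aln_at(g, "chrT", hp$start - 18L, hp$start + 2L, "+"),   # 18 nt flank / 2 nt hairpin
    aln_at(g, "chrT", hp$end - 2L, hp$end + 18L, "+"))       # 3p mirror case
  cand <- collect_offset_reads(a, list(e = fs$eh), cfg)
  expect_identical(nrow(cand), 3L)
  expect_identical(cand$arm, c("5p", "5p", "3p"))
  expect_setequal(cand$start[cand$arm == "5p"],
                  c(hp$start - 25L, hp$start - 18L))
})

test_that("minus-strand flanks map to the transcript arms", {
  fs <- flank_setup(seed = 42, strand = "-")
  hp <- fs$w$hp; g <- fs$w$genome
  # genomic right of a minus-strand hairpin is its transcript 5' side
  a <- rbind(aln_at(g, "chrT", hp$end + 3L, hp$end + 22L, "-"),
             aln_at(g, "chrT", hp$start - 22L, hp$start - 3L, "-"))
  cand <- collect_offset_reads(a, list(e = fs$eh), pipeline_config())
  expect_identical(cand$arm[cand$start == hp$end + 3L], "5p")
  expect_identical(cand$arm[cand$start == hp$start - 22L], "3p")
})

test_that("modal isoform selection follows counts then the tie-breaks", {
  fs <- flank_setup(seed = 43)
  hp <- fs$w$hp; g <- fs$w$genome
  x <- read_at(g, "chrT", hp$start - 20L, hp$start, "+")
  y <- read_at(g, "chrT", hp$start - 19L, hp$start, "+")
  a <- rbind(aln_at(g, "chrT", hp$start - 20L, hp$start, "+"),
             aln_at(g, "chrT", hp$start - 19L, hp$start, "+"))
  cand <- collect_offset_reads(a, list(e = fs$eh), pipeline_config())
  # clear majority
  grp <- group_isoforms(cand, c(2, 1) |> stats::setNames(c(x, y)))
  expect_identical(grp[[1L]]$modal_seq, x)
  # tie: the longer sequence wins
  grp2 <- group_isoforms(cand, c(2, 2) |> stats::setNames(c(y, x)))
  expect_identical(grp2[[1L]]$modal_seq, x)
  # random multisets match an exhaustive max oracle on counts
  set.seed(431)
  for (i in 1:10) {
    counts <- stats::setNames(sample(1:50, 2L, replace = FALSE), c(x, y))
    grp3 <- group_isoforms(cand, counts)
    expect_identical(grp3[[1L]]$modal_seq,
                     names(counts)[which.max(counts)])
  }
})

test_that("five-prime consistency is the modal 5'-end mass fraction", {
  fs <- flank_setup(seed = 44)
  hp <- fs$w$hp; g <- fs$w$genome
  starts <- c(hp$start - 20L, hp$start - 20L, hp$start - 18L, hp$start - 19L)
  lens <- c(20L, 19L, 18L, 17L)
  a <- do.call(rbind, lapply(seq_along(starts), function(i) {
    aln_at(g, "chrT", starts[i], starts[i] + lens[i], "+")
  }))
  cand <- collect_offset_reads(a, list(e = fs$eh), pipeline_config())
  counts <- stats::setNames(c(4, 3, 2, 1), a$seq)
  grp <- group_isoforms(cand, counts)[[1L]]
  # mass at 5' starts: -20 -> 4+3, -18 -> 2, -19 -> 1
  expect_equal(five_prime_consistency(grp), 7 / 10)
  # all reads share one 5' start -> 1.0
  one <- grp; one$members <- grp$members[grp$members$start == hp$start - 20L, ]
  expect_equal(five_prime_consistency(one), 1.0)
  # symmetric split -> 0.5
  half <- grp
  half$members <- grp$members[1:2, ]
  half$members$count <- c(2, 2)
  half$members$start <- c(hp$start - 20L, hp$start - 18L)
  expect_equal(five_prime_consistency(half), 0.5)
})

test_that("quantification counts containment in the widened reference locus", {
  fs <- flank_setup(seed = 45)
  hp <- fs$w$hp; g <- fs$w$genome
  cfg <- pipeline_config()
  modal_start <- hp$start - 19L
  modal <- read_at(g, "chrT", modal_start, hp$start, "+")
  in2 <- read_at(g, "chrT", modal_start - 2L, hp$start + 1L, "+")
  out3 <- read_at(g, "chrT", modal_start - 3L, hp$start, "+")
  mm1 <- mutate_at(modal, 9L)
  a <- rbind(aln_at(g, "chrT", modal_start, hp$start, "+"),
             aln_at(g, "chrT", modal_start - 2L, hp$start + 1L, "+"),
             aln_at(g, "chrT", modal_start - 3L, hp$start, "+"))
  a <- rbind(a, data.frame(seq = mm1, chrom = "chrT", start = modal_start,
                           end = hp$start, strand = "+", mismatches = 1L))
  cand <- collect_offset_reads(a, list(e = fs$eh), cfg)
  counts_total <- stats::setNames(c(7, 3, 2, 4), c(modal, in2, out3, mm1))
  grp <- group_isoforms(cand, counts_total)[[1L]]
  expect_identical(grp$modal_seq, modal)
  lc <- matrix(counts_total, ncol = 1L,
               dimnames = list(names(counts_total), "lib1"))
  denom <- c(lib1 = 1e6)  # unit denominator: RPM == raw count
  # exact mode: only the zero-mismatch reads inside the widened locus
  call0 <- quantify_morna(grp, a, lc, denom, cfg)
  expect_equal(unname(call0$counts[["lib1"]]), 7 + 3)
  # single library whose only flank read is the modal sequence, count 7
  lc_modal <- matrix(7, 1L, 1L, dimnames = list(modal, "lib1"))
  grp_modal <- group_isoforms(cand[cand$seq == modal, , drop = FALSE],
                              stats::setNames(7, modal))[[1L]]
  expect_equal(unname(quantify_morna(grp_modal, a[1L, ], lc_modal, denom,
                                     cfg)$counts[["lib1"]]), 7)
  # tolerant mode additionally counts the 1-mismatch isomoR
  call2 <- quantify_morna(grp, a, lc, denom,
                          pipeline_config(quant_mismatches = 2))
  expect_equal(unname(call2$counts[["lib1"]]), 7 + 3 + 4)
  # the read starting 3 nt outside the widened locus is never counted
  expect_false(out3 %in% a$seq[a$start >= modal_start - 2L])
})

test_that("tolerant-mode counts dominate exact-mode counts", {
  set.seed(46)
  for (i in 1:4) {
    fs <- flank_setup(seed = 460 + i, strand = sample(c("+", "-"), 1L))
    hp <- fs$w$hp; g <- fs$w$genome
    rows <- list()
    for (j in 1:12) {
      if (hp$strand == "+") {
        s <- hp$start - sample(15:22, 1L)
        e <- s + sample(15:21, 1L)
      } else {
        e <- hp$end + sample(15:22, 1L)
        s <- e - sample(15:21, 1L)
      }
      r <- aln_at(g, "chrT", s, e, hp$strand)
      if (stats::runif(1L) < 0.4) {
        r$seq <- mutate_at(r$seq, sample(nchar(r$seq), sample(1:2, 1L)))
        r$mismatches <- NA
        r$mismatches <- sum(strsplit(r$seq, "")[[1L]] !=
                              strsplit(read_at(g, "chrT", s, e, hp$strand),
                                       "")[[1L]])
      }
      rows[[j]] <- r
    }
    a <- do.call(rbind, rows)
    a <- a[!duplicated(a$seq), ]
    cand <- collect_offset_reads(a, list(e = fs$eh), pipeline_config())
    if (nrow(cand) == 0L) next
    counts_total <- stats::setNames(sample(1:9, nrow(a), TRUE), a$seq)
    grp <- group_isoforms(cand, counts_total)
    lc <- matrix(counts_total, ncol = 1L,
                 dimnames = list(names(counts_total), "lib1"))
    for (g1 in grp) {
      c0 <- quantify_morna(g1, a, lc, c(lib1 = 1e6), pipeline_config())
      c2 <- quantify_morna(g1, a, lc, c(lib1 = 1e6),
                           pipeline_config(quant_mismatches = 2))
      expect_gte(unname(c2$counts[["lib1"]]), unname(c0$counts[["lib1"]]))
    }
  }
})

test_that("size-distribution filters gate the length histograms", {
  fs <- flank_setup(seed = 47)
  hp <- fs$w$hp; g <- fs$w$genome
  cfg <- pipeline_config()
  modal_start <- hp$start - 19L
  a <- aln_at(g, "chrT", modal_start, hp$start, "+")
  cand <- collect_offset_reads(a, list(e = fs$eh), cfg)
  # 10 reads at 1 RPM (denominator 1e7 -> rpm 1): histogram mass at 19
  lc <- matrix(10, 1L, 1L, dimnames = list(a$seq, "lib1"))
  grp <- group_isoforms(cand, stats::setNames(10, a$seq))
  calls <- lapply(grp, quantify_morna, alignments = a, lib_counts = lc,
                  denominators = c(lib1 = 1e7), cfg = cfg)
  st <- morna_stats(grp, calls, lc, cfg)
  expect_identical(names(st$length_dist$mor5p), "19")
  expect_equal(unname(st$length_dist$mor5p[["19"]]), 10)
  # below the 5-read floor nothing enters the histogram
  lc2 <- matrix(4, 1L, 1L, dimnames = list(a$seq, "lib1"))
  grp2 <- group_isoforms(cand, stats::setNames(4, a$seq))
  calls2 <- lapply(grp2, quantify_morna, alignments = a, lib_counts = lc2,
                   denominators = c(lib1 = 1e7), cfg = cfg)
  st2 <- morna_stats(grp2, calls2, lc2, cfg)
  expect_length(st2$length_dist$mor5p, 0L)
})

test_that("the expression correlation filters pairs and matches rank-Pearson", {
  cfg <- pipeline_config()
  # perfectly monotone pairs
  expect_equal(mir_mor_correlation(1:10, (1:10)^2, cfg)$rho, 1.0)
  # a pair with moR RPM 0.3 is excluded
  out <- mir_mor_correlation(c(1, 2, 3, 4), c(5, 0.3, 2, 1), cfg)
  expect_identical(out$n_pairs, 3L)
  # 20-pair fixture equals the rank-then-Pearson oracle
  set.seed(48)
  mir <- stats::runif(20, 0.6, 50)
  mor <- stats::runif(20, 0.6, 20)
  got <- mir_mor_correlation(mir, mor, cfg)
  expect_identical(got$n_pairs, 20L)
  expect_equal(got$rho, rank_pearson(mir, mor))
  # undefined below 3 surviving pairs
  expect_true(is.na(mir_mor_correlation(c(1, 2), c(1, 2), cfg)$rho))
})

test_that("count-matrix export applies the RPM inclusion filter", {
  cfg <- pipeline_config()
  counts <- matrix(c(5, 50, 0, 7), 2L, 2L,
                   dimnames = list(c("f.low", "f.hi"), c("a", "b")))
  rpm <- matrix(c(0.5, 2.0, 0.5, 0.9), 2L, 2L,
                dimnames = dimnames(counts))
  out <- export_count_matrix(counts, rpm, cfg)
  expect_identical(rownames(out), "f.hi")
  expect_identical(out[1L, ], c(a = 50L, b = 7L))
  # round-trip through TSV
  tf <- tempfile(fileext = ".tsv")
  export_count_matrix(counts, rpm, cfg, file = tf)
  back <- utils::read.delim(tf)
  expect_identical(back$feature, "f.hi")
})
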