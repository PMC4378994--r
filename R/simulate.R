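# Synthetic-data generator: builds a fully specified reference (genome,
# hairpin annotations, ncRNA decoys, conservation track) and sequencing
# libraries with planted miRNA/moRNA populations plus per-read ground
# truth, so every pipeline stage is testable without external downloads.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline was built for: an
#' adapter-ligated small RNA library with planted moR-5p/miR-5p/miR-3p/
#' moR-3p populations, 5'-end consistency 0.97, a moR-5p length peak at
#' 19 nt (range 16-26), moR-3p lengths 16-29, a 58% 5'-arm usage bias,
#' per-base sequencing errors, and background reads from other ncRNA
#' classes.
#'
#' @param rng_seed master seed; identical configuration (including seed)
#'   yields byte-identical outputs.
#' @param n_hairpins number of miRNA hairpins embedded in the genome.
#' @param hairpin_len_range precursor length range in nt.
#' @param mature_len mature miRNA length in nt.
#' @param spacing minimum separation between embedded features in nt.
#' @param clustered logical; also place one hairpin pair fewer than 60 nt
#'   apart to exercise shared-flank assignment.
#' @param n_single_arm number of hairpins annotated with only one mature.
#' @param n_morna number of planted moRNA features.
#' @param arm_bias_5p probability that a moRNA read derives from the 5'
#'   arm.
#' @param five_prime_consistency probability that a small RNA read keeps
#'   its feature's modal 5' end (isoform model).
#' @param mir_five_prime_consistency same for mature miRNA reads.
#' @param mir_len_jitter pool of 3'-end length offsets for isomiR reads
#'   (sampled uniformly; repeat 0 to weight it).
#' @param mor5p_lens,mor5p_len_probs moR-5p isoform length model (peak at
#'   19 nt).
#' @param mor3p_lens moR-3p length range; each feature keeps its own modal
#'   length with probability \code{mor3p_modal_prob}, otherwise uniform.
#' @param mor3p_modal_prob see above.
#' @param p_morna,p_background,p_dimer,p_homopolymer,p_short,p_lowq
#'   per-read category probabilities (the remainder is mature miRNA
#'   reads).
#' @param tail_lowq_frac fraction of good reads receiving a 1-2 base
#'   low-quality 3' tail.
#' @param error_rate per-base substitution error rate.
#' @param adapter 3' adapter sequence ligated to every insert.
#' @param library_size reads per simulated library.
#' @param n_decoys_per_class,decoy_len_range,fragments_per_decoy background
#'   ncRNA decoy model: per class, decoy sequences embedded in the genome,
#'   each expressing a finite pool of clonal fragments.
#' @param background_classes decoy ncRNA class labels.
#' @param conserved_prob probability that a hairpin locus is planted as
#'   conserved.
#' @param good_q,bad_q the two Phred states of the quality model.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_hairpins = 20L,
                       hairpin_len_range = c(70L, 90L),
                       mature_len = 22L,
                       spacing = 100L,
                       clustered = FALSE,
                       n_single_arm = 0L,
                       n_morna = 12L,
                       arm_bias_5p = 0.58,
                       five_prime_consistency = 0.97,
                       mir_five_prime_consistency = 0.80,
                       mir_len_jitter = c(-2L, -1L, 0L, 0L, 0L, 0L, 1L, 2L),
                       mor5p_lens = 16:26,
                       mor5p_len_probs = c(0.01, 0.03, 0.08, 0.62, 0.10,
                                           0.06, 0.04, 0.02, 0.02, 0.01,
                                           0.01),
                       mor3p_lens = 16:29,
                       mor3p_modal_prob = 0.55,
                       p_morna = 0.024,
                       p_background = 0.25,
                       p_dimer = 0.02,
                       p_homopolymer = 0.01,
                       p_short = 0.02,
                       p_lowq = 0.04,
                       tail_lowq_frac = 0.05,
                       error_rate = 0.001,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       library_size = 50000L,
                       n_decoys_per_class = 2L,
                       decoy_len_range = c(80L, 160L),
                       fragments_per_decoy = 4L,
                       background_classes = c("snRNA", "snoRNA", "rRNA",
                                              "mt_tRNA", "miscRNA", "piRNA",
                                              "tRNA", "repeat"),
                       conserved_prob = 0.65,
                       good_q = 38L,
                       bad_q = 8L) {
  cfg <- as.list(environment())
  probs <- c(cfg$arm_bias_5p, cfg$five_prime_consistency,
             cfg$mir_five_prime_consistency, cfg$mor3p_modal_prob,
             cfg$p_morna, cfg$p_background, cfg$p_dimer, cfg$p_homopolymer,
             cfg$p_short, cfg$p_lowq, cfg$tail_lowq_frac, cfg$error_rate,
             cfg$conserved_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$library_size < 1L) stop("library_size must be at least 1")
  if (abs(sum(cfg$mor5p_len_probs) - 1) > 1e-8)
    stop("mor5p_len_probs must sum to 1")
  if (length(cfg$mor5p_len_probs) != length(cfg$mor5p_lens))
    stop("mor5p length model is inconsistent")
  if (cfg$n_morna > cfg$n_hairpins)
    stop("cannot plant more moRNA features than hairpins")
  structure(cfg, class = "sim_config")
}

# sample() that treats a length-1 pool as a constant, not as 1:n
sample_pool <- function(x, n, prob = NULL) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE,
                                             prob = prob)
}

# Draw a random spacer of at least `min` nt (up to min + 40).
random_spacer <- function(min) {
  random_dna(1L, min + sample.int(41L, 1L) - 1L)
}

#' Simulate the reference layer
#'
#' Builds a single-chromosome genome embedding the hairpins (with at least
#' \code{spacing} nt separation; an extra close pair under
#' \code{clustered}), the decoy ncRNAs, planted moRNA feature definitions,
#' and a conservation track reflecting each hairpin's planted
#' conserved/nonconserved label.
#'
#' @param cfg a \code{sim_config}.
#' @return object of class \code{sim_reference}: genome, hairpins,
#'   features (planted moRNAs), decoys, fragments, conservation,
#'   conserved_labels, cfg.
#' @export
simulate_reference <- function(cfg = sim_config()) {
  set.seed(cfg$rng_seed)
  chrom <- "sim1"
  n_hp <- cfg$n_hairpins
  hp_len <- sample(seq(cfg$hairpin_len_range[1L], cfg$hairpin_len_range[2L]),
                   n_hp, replace = TRUE)
  if (min(hp_len) < 2L * cfg$mature_len + 4L)
    stop("genome too small for requested features: hairpins cannot hold two matures")
  hp_seq <- vapply(hp_len, function(l) random_dna(1L, l), character(1L))
  hp_strand <- sample(c("+", "-"), n_hp, replace = TRUE)
  single_arm <- rep(FALSE, n_hp)
  if (cfg$n_single_arm > 0L)
    single_arm[sample.int(n_hp, min(cfg$n_single_arm, n_hp))] <- TRUE
  single_arm_is_5p <- sample(c(TRUE, FALSE), n_hp, replace = TRUE)

  # assemble the chromosome: spacer, feature, spacer, ...
  pieces <- list(random_spacer(cfg$spacing))
  hp_start <- integer(n_hp)
  pos <- nchar(pieces[[1L]])
  cluster_pair <- if (cfg$clustered && n_hp >= 2L) 2L else 0L
  for (i in seq_len(n_hp)) {
    g <- if (hp_strand[i] == "+") hp_seq[i] else revcomp(hp_seq[i])
    hp_start[i] <- pos
    pieces[[length(pieces) + 1L]] <- g
    pos <- pos + nchar(g)
    gap <- if (i + 1L == cluster_pair) random_dna(1L, 45L)
           else random_spacer(cfg$spacing)
    pieces[[length(pieces) + 1L]] <- gap
    pos <- pos + nchar(gap)
  }
  decoys <- list()
  fragments <- list()
  for (cl in cfg$background_classes) {
    seqs <- character(cfg$n_decoys_per_class)
    for (d in seq_len(cfg$n_decoys_per_class)) {
      dl <- sample(seq(cfg$decoy_len_range[1L], cfg$decoy_len_range[2L]), 1L)
      s <- random_dna(1L, dl)
      seqs[d] <- s
      pieces[[length(pieces) + 1L]] <- s
      pos <- pos + dl
      gap <- random_spacer(cfg$spacing)
      pieces[[length(pieces) + 1L]] <- gap
      pos <- pos + nchar(gap)
      for (f in seq_len(cfg$fragments_per_decoy)) {
        fl <- sample(16:28, 1L)
        fs <- sample.int(dl - fl + 1L, 1L)
        fragments[[length(fragments) + 1L]] <- data.frame(
          class = cl, seq = substr(s, fs, fs + fl - 1L),
          weight = stats::rexp(1L), stringsAsFactors = FALSE)
      }
    }
    names(seqs) <- paste0("sim-", cl, "-", seq_len(cfg$n_decoys_per_class))
    decoys[[cl]] <- seqs
  }
  genome <- stats::setNames(paste(unlist(pieces), collapse = ""), chrom)
  glen <- nchar(genome[[1L]])

  hairpins <- vector("list", n_hp)
  for (i in seq_len(n_hp)) {
    s <- hp_start[i]; e <- s + hp_len[i]
    # matures occupy the precursor ends (transcript orientation)
    t5 <- c(0L, cfg$mature_len)
    t3 <- c(hp_len[i] - cfg$mature_len, hp_len[i])
    to_genome <- function(t) {
      if (hp_strand[i] == "+") c(s + t[1L], s + t[2L])
      else c(e - t[2L], e - t[1L])
    }
    m5 <- to_genome(t5); m3 <- to_genome(t3)
    if (single_arm[i]) {
      if (single_arm_is_5p[i]) m3 <- NULL else m5 <- NULL
    }
    hairpins[[i]] <- hairpin_record(sprintf("sim-mir-%03d", i), chrom,
                                    s, e, hp_strand[i], hp_seq[i],
                                    mature5p = m5, mature3p = m3)
  }
  names(hairpins) <- vapply(hairpins, `[[`, character(1L), "name")

  # planted moRNA features: one per selected hairpin, arm ~ Bernoulli(bias)
  sel <- sample.int(n_hp, cfg$n_morna)
  feat <- list()
  for (i in sel) {
    hp <- hairpins[[i]]
    arm <- if (stats::runif(1L) < cfg$arm_bias_5p) "5p" else "3p"
    mlen <- if (arm == "5p")
      cfg$mor5p_lens[which.max(cfg$mor5p_len_probs)]
    else sample_pool(cfg$mor3p_lens, 1L)
    if (arm == "5p") {
      # modal isomoR ends exactly at the precursor 5' boundary
      iv <- if (hp$strand == "+") c(hp$start - mlen, hp$start)
            else c(hp$end, hp$end + mlen)
    } else {
      iv <- if (hp$strand == "+") c(hp$end, hp$end + mlen)
            else c(hp$start - mlen, hp$start)
    }
    refseq <- substr(genome[[1L]], iv[1L] + 1L, iv[2L])
    if (hp$strand == "-") refseq <- revcomp(refseq)
    feat[[length(feat) + 1L]] <- data.frame(
      name = morna_name(hp$name, arm), hairpin = hp$name, arm = arm,
      chrom = chrom, start = iv[1L], end = iv[2L], strand = hp$strand,
      ref_seq = refseq, modal_len = mlen, stringsAsFactors = FALSE)
  }
  features <- if (length(feat) > 0L) do.call(rbind, feat) else
    data.frame(name = character(0L), hairpin = character(0L),
               arm = character(0L), chrom = character(0L),
               start = integer(0L), end = integer(0L),
               strand = character(0L), ref_seq = character(0L),
               modal_len = integer(0L), stringsAsFactors = FALSE)
  rownames(features) <- NULL

  conserved <- stats::runif(n_hp) < cfg$conserved_prob
  cons_rows <- list()
  for (i in seq_len(n_hp)) {
    s <- max(0L, hp_start[i] - 30L)
    e <- min(glen, hp_start[i] + hp_len[i] + 30L)
    brk <- unique(c(seq(s, e, by = 10L), e))
    for (j in seq_len(length(brk) - 1L)) {
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        chrom = chrom, start = brk[j], end = brk[j + 1L],
        score = round(if (conserved[i]) stats::runif(1L, 0.6, 0.95)
                      else stats::runif(1L, 0.05, 0.30), 3L),
        stringsAsFactors = FALSE)
    }
  }
  conservation <- do.call(rbind, cons_rows)
  frag <- do.call(rbind, fragments)
  frag$weight <- frag$weight / sum(frag$weight)
  structure(list(genome = genome, hairpins = hairpins, features = features,
                 decoys = decoys, fragments = frag,
                 conservation = conservation,
                 conserved_labels = stats::setNames(conserved,
                                                    names(hairpins)),
                 cfg = cfg),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf(
    "<sim reference: %d nt genome, %d hairpins, %d planted moRNAs, %d decoy classes>\n",
    nchar(x$genome[[1L]]), length(x$hairpins), nrow(x$features),
    length(x$decoys)))
  invisible(x)
}

#' Write the simulated reference to files
#'
#' Emits genome FASTA, hairpin GFF3, one decoy FASTA per ncRNA class, and
#' the conservation bedGraph.
#'
#' @param ref a \code{sim_reference}.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_sim_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "hairpins.gff3"),
             conservation = file.path(dir, "conservation.bedGraph"))
  write_fasta(ref$genome, paths[["genome"]])
  write_hairpin_gff3(ref$hairpins, paths[["gff"]])
  write_bedgraph(ref$conservation, paths[["conservation"]])
  for (cl in names(ref$decoys)) {
    p <- file.path(dir, paste0("decoy_", cl, ".fa"))
    write_fasta(ref$decoys[[cl]], p)
    paths[[paste0("decoy_", cl)]] <- p
  }
  paths
}

# Mutate sequences in place with per-base substitution errors; returns
# list(seq, n_errors, error_pos). Only reads drawn with >= 1 error are
# touched.
apply_errors <- function(seqs, error_rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  pos_str <- character(length(seqs))
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    p <- sort(sample.int(nchar(seqs[i]), n_err[i]))
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (j in p) b[j] <- sample(setdiff(bases, b[j]), 1L)
    seqs[i] <- paste(b, collapse = "")
    pos_str[i] <- paste(p, collapse = ",")
  }
  list(seq = seqs, n_errors = n_err, error_pos = pos_str)
}

# Sample isoform intervals for feature-derived reads. anchor5 is the genome
# coordinate of the modal transcript 5' end (start on +, end on -).
isoform_intervals <- function(strand, anchor5, shift, len) {
  g_start <- ifelse(strand == "+", anchor5 + shift, anchor5 - shift - len)
  g_end <- g_start + len
  cbind(start = g_start, end = g_end)
}

#' Simulate a sequencing library
#'
#' Draws \code{cfg$library_size} reads: planted moRNA and mature miRNA
#' isoforms (5'-end consistency and length models), clonal background
#' fragments from the decoy ncRNAs, and artifact reads (adapter dimers,
#' homopolymers, short inserts, low-quality reads). Every read carries the
#' 3' adapter and a two-state (good/bad) quality string; per-read ground
#' truth records the originating feature and error positions.
#'
#' @param ref a \code{sim_reference}.
#' @param cfg a \code{sim_config}; defaults to the one inside \code{ref}.
#' @param lib_index integer library index; reads and the RNG stream are
#'   salted with it so multi-library experiments differ.
#' @param lib_name library name used in read ids.
#' @return object of class \code{sim_library}: \code{reads} (read_id, seq,
#'   qual), \code{truth} (reads table, realized feature counts, expected
#'   in-window quantification fractions), \code{name}.
#' @export
simulate_library <- function(ref, cfg = ref$cfg, lib_index = 1L,
                             lib_name = paste0("lib", lib_index)) {
  set.seed(cfg$rng_seed + 10007L * lib_index)
  N <- cfg$library_size
  genome <- ref$genome[[1L]]
  p_mirna <- 1 - (cfg$p_morna + cfg$p_background + cfg$p_dimer +
                    cfg$p_homopolymer + cfg$p_short + cfg$p_lowq)
  if (p_mirna < 0) stop("category probabilities exceed 1")
  cats <- sample(c("morna", "mirna", "background", "dimer", "homopolymer",
                   "short", "lowq"), N, replace = TRUE,
                 prob = c(cfg$p_morna, p_mirna, cfg$p_background,
                          cfg$p_dimer, cfg$p_homopolymer, cfg$p_short,
                          cfg$p_lowq))
  seqs <- character(N)
  origin <- character(N)
  feats <- ref$features
  if (nrow(feats) == 0L) cats[cats == "morna"] <- "mirna"
  f5 <- which(feats$arm == "5p")
  f3 <- which(feats$arm == "3p")

  # planted moRNA reads: arm per read ~ Bernoulli(arm_bias_5p)
  im <- which(cats == "morna")
  if (length(im) > 0L) {
    use5 <- stats::runif(length(im)) < cfg$arm_bias_5p
    if (length(f5) == 0L) use5[] <- FALSE
    if (length(f3) == 0L) use5[] <- TRUE
    fid <- integer(length(im))
    fid[use5] <- f5[sample.int(length(f5), sum(use5), replace = TRUE)]
    fid[!use5] <- f3[sample.int(length(f3), sum(!use5), replace = TRUE)]
    fr <- feats[fid, , drop = FALSE]
    consistent <- stats::runif(length(im)) < cfg$five_prime_consistency
    shift <- ifelse(consistent, 0L,
                    sample(c(-2L, -1L, 1L, 2L), length(im), replace = TRUE))
    len <- integer(length(im))
    is5 <- fr$arm == "5p"
    len[is5] <- sample_pool(cfg$mor5p_lens, sum(is5),
                            prob = cfg$mor5p_len_probs)
    keep_modal <- stats::runif(sum(!is5)) < cfg$mor3p_modal_prob
    len3 <- sample_pool(cfg$mor3p_lens, sum(!is5))
    len3[keep_modal] <- fr$modal_len[!is5][keep_modal]
    len[!is5] <- len3
    anchor5 <- ifelse(fr$strand == "+", fr$start, fr$end)
    iv <- isoform_intervals(fr$strand, anchor5, shift, len)
    s <- substr(rep(genome, length(im)), iv[, "start"] + 1L, iv[, "end"])
    minus <- fr$strand == "-"
    s[minus] <- revcomp(s[minus])
    seqs[im] <- s
    origin[im] <- fr$name
  }

  # mature miRNA reads (isomiR model)
  ii <- which(cats == "mirna")
  if (length(ii) > 0L) {
    arms <- do.call(rbind, lapply(ref$hairpins, function(hp) {
      out <- list()
      if (!is.null(hp$mature5p))
        out[[length(out) + 1L]] <- data.frame(
          hairpin = hp$name, arm = "5p", strand = hp$strand,
          start = hp$mature5p[1L], end = hp$mature5p[2L],
          stringsAsFactors = FALSE)
      if (!is.null(hp$mature3p))
        out[[length(out) + 1L]] <- data.frame(
          hairpin = hp$name, arm = "3p", strand = hp$strand,
          start = hp$mature3p[1L], end = hp$mature3p[2L],
          stringsAsFactors = FALSE)
      do.call(rbind, out)
    }))
    aid <- sample.int(nrow(arms), length(ii), replace = TRUE)
    ar <- arms[aid, , drop = FALSE]
    consistent <- stats::runif(length(ii)) < cfg$mir_five_prime_consistency
    shift <- ifelse(consistent, 0L,
                    sample(c(-2L, -1L, 1L, 2L), length(ii), replace = TRUE))
    len <- cfg$mature_len + sample_pool(cfg$mir_len_jitter, length(ii))
    anchor5 <- ifelse(ar$strand == "+", ar$start, ar$end)
    iv <- isoform_intervals(ar$strand, anchor5, shift, len)
    s <- substr(rep(genome, length(ii)), iv[, "start"] + 1L, iv[, "end"])
    minus <- ar$strand == "-"
    s[minus] <- revcomp(s[minus])
    seqs[ii] <- s
    origin[ii] <- mirna_name(ar$hairpin, ar$arm)
  }

  # clonal background fragments
  ib <- which(cats == "background")
  if (length(ib) > 0L) {
    fid <- sample.int(nrow(ref$fragments), length(ib), replace = TRUE,
                      prob = ref$fragments$weight)
    seqs[ib] <- ref$fragments$seq[fid]
    origin[ib] <- ref$fragments$class[fid]
  }

  # artifacts
  id <- which(cats == "dimer")
  seqs[id] <- ""; origin[id] <- "dimer"
  ih <- which(cats == "homopolymer")
  if (length(ih) > 0L) {
    seqs[ih] <- strrep("A", sample(16:24, length(ih), replace = TRUE))
    origin[ih] <- "homopolymer"
  }
  is <- which(cats == "short")
  if (length(is) > 0L) {
    seqs[is] <- random_dna(length(is), 10L)
    origin[is] <- "short"
  }
  il <- which(cats == "lowq")
  if (length(il) > 0L) {
    fid <- sample.int(nrow(ref$fragments), length(il), replace = TRUE)
    seqs[il] <- ref$fragments$seq[fid]
    origin[il] <- "lowq"
  }

  full <- paste0(seqs, cfg$adapter)
  err <- apply_errors(full, cfg$error_rate)
  full <- err$seq
  goodc <- intToUtf8(cfg$good_q + 33L)
  badc <- intToUtf8(cfg$bad_q + 33L)
  qual <- strrep(goodc, nchar(full))
  qual[il] <- strrep(badc, nchar(full[il]))
  tail_bad <- which(cats != "lowq" &
                      stats::runif(N) < cfg$tail_lowq_frac)
  ntail <- sample(1:2, length(tail_bad), replace = TRUE)
  substr(qual[tail_bad],
         nchar(qual[tail_bad]) - ntail + 1L,
         nchar(qual[tail_bad])) <- strrep(badc, 2L)

  read_id <- sprintf("%s_r%06d", lib_name, seq_len(N))
  reads <- data.frame(read_id = read_id, seq = full, qual = qual,
                      stringsAsFactors = FALSE)

  # expected fraction of a feature's reads that fall inside the widened
  # modal locus (the quantification window), from the isoform model alone
  p_window <- if (nrow(feats) == 0L) numeric(0L) else
    vapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    shift_p <- c(cfg$five_prime_consistency,
                 rep((1 - cfg$five_prime_consistency) / 4, 4L))
    shifts <- c(0L, -2L, -1L, 1L, 2L)
    if (f$arm == "5p") {
      lens <- cfg$mor5p_lens; lp <- cfg$mor5p_len_probs
    } else {
      lens <- cfg$mor3p_lens
      lp <- rep((1 - cfg$mor3p_modal_prob) / length(cfg$mor3p_lens),
                length(cfg$mor3p_lens))
      lp[lens == f$modal_len] <- lp[lens == f$modal_len] +
        cfg$mor3p_modal_prob
    }
    p <- 0
    for (si in seq_along(shifts)) for (li in seq_along(lens)) {
      if (shifts[si] >= -2L && shifts[si] + lens[li] <= f$modal_len + 2L)
        p <- p + shift_p[si] * lp[li]
    }
    p
  }, numeric(1L))
  realized <- table(factor(origin[cats == "morna"], levels = feats$name))
  truth <- list(
    features = cbind(feats,
                     planted_count = as.integer(realized[feats$name]),
                     p_window = p_window),
    reads = data.frame(read_id = read_id, category = cats, origin = origin,
                       n_errors = err$n_errors, error_pos = err$error_pos,
                       stringsAsFactors = FALSE),
    composition = table(cats))
  structure(list(reads = reads, truth = truth, name = lib_name),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim library %s: %d reads>\n", x$name, nrow(x$reads)))
  print(x$truth$composition)
  invisible(x)
}

#' Evaluate pipeline recovery against planted truth
#'
#' A planted moRNA is recovered when a call on the same (hairpin, arm) is
#' detected at or above \code{min_reads} total raw count and its reference
#' sequence equals the planted modal isoform. Precision counts calls at or
#' above threshold that correspond to planted features. Abundance recovery
#' compares each call's raw count with the expected in-window read count
#' (planted count times the isoform-model window fraction), for features
#' planted at or above \code{abundance_min}.
#'
#' @param calls list of \code{morna_call} (or a \code{morna_result}).
#' @param truth a \code{sim_library} truth component (or the library).
#' @param min_reads detection threshold in reads. Default 5.
#' @param abundance_min minimum planted count for abundance comparison.
#'   Default 50.
#' @return list: recall, precision, n_planted, n_detected, abundance
#'   (data.frame with per-feature expected/observed/rel_err), seq_identical
#'   (fraction of recovered calls whose reference equals the planted
#'   modal sequence).
#' @export
evaluate_recovery <- function(calls, truth, min_reads = 5,
                              abundance_min = 50) {
  if (inherits(calls, "morna_result")) calls <- calls$calls
  if (inherits(truth, "sim_library")) truth <- truth$truth
  feats <- truth$features
  call_key <- vapply(calls, function(x) paste0(x$hairpin, ":", x$arm),
                     character(1L))
  call_total <- vapply(calls, function(x) sum(x$counts), numeric(1L))
  detected <- call_total >= min_reads
  feat_key <- paste0(feats$hairpin, ":", feats$arm)
  hit <- match(feat_key, call_key)
  recovered <- vapply(seq_along(hit), function(i) {
    !is.na(hit[i]) && detected[hit[i]] &&
      calls[[hit[i]]]$ref_seq == feats$ref_seq[i]
  }, logical(1L))
  n_planted <- nrow(feats)
  recall <- if (n_planted > 0L) sum(recovered) / n_planted else NA_real_
  n_det <- sum(detected)
  precision <- if (n_det > 0L)
    sum(call_key[detected] %in% feat_key) / n_det else NA_real_
  ab <- feats[feats$planted_count >= abundance_min, , drop = FALSE]
  if (nrow(ab) > 0L) {
    idx <- match(paste0(ab$hairpin, ":", ab$arm), call_key)
    observed <- ifelse(is.na(idx), 0, call_total[idx])
    expected <- ab$planted_count * ab$p_window
    abundance <- data.frame(name = ab$name, planted = ab$planted_count,
                            expected = expected, observed = observed,
                            rel_err = abs(observed - expected) / expected,
                            stringsAsFactors = FALSE)
  } else {
    abundance <- data.frame(name = character(0L), planted = integer(0L),
                            expected = numeric(0L), observed = numeric(0L),
                            rel_err = numeric(0L))
  }
  matched <- vapply(seq_along(hit), function(i) {
    !is.na(hit[i]) && detected[hit[i]]
  }, logical(1L))
  list(recall = recall, precision = precision, n_planted = n_planted,
       n_detected = n_det, abundance = abundance,
       seq_identical = if (sum(matched) > 0L)
         sum(recovered) / sum(matched) else NA_real_)
}
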