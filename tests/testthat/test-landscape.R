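mut_pos <- function(pos, chrom = "chr1") {
  data.frame(line_id = "L1", chrom = chrom, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

test_that("per-chromosome spacing and rate are computed from lengths", {
  g <- genome_model(c(chr1 = 1e7, chr2 = 5e6))
  f <- chromosome_frequency(mut_pos(seq(1e6, 9e6, by = 2e6)), g)
  expect_equal(f$count, c(5L, 0L))
  expect_equal(f$kb_per_mutation[1], 2000)
  expect_equal(f$per_bp_rate[2], 0)
  expect_true(is.na(f$kb_per_mutation[2]))
  expect_error(chromosome_frequency(mut_pos(1, chrom = "chrX"), g),
               "absent from genome model")
})

test_that("window tiling is 1-based inclusive with a ragged tail", {
  g <- genome_model(c(chr1 = 2.5e6))
  w <- window_counts(mut_pos(c(1, 1e6, 1e6 + 1, 2.4e6)), g, 1e6)
  expect_equal(nrow(w), 3)
  expect_equal(w$end, c(1e6, 2e6, 2.5e6))
  # a mutation at exactly 1,000,000 belongs to the first window
  expect_equal(w$count, c(2L, 1L, 1L))
  expect_equal(w$frequency[3], 1 / 5e5)
})

test_that("window counts equal brute-force binning on random positions", {
  set.seed(123)
  g <- genome_model(c(chr1 = 3.7e6))
  pos <- sample.int(3.7e6, 10000, replace = TRUE)
  w <- window_counts(mut_pos(pos), g, 1e5)
  expect_equal(w$count, oracle_window_counts(pos, 3.7e6, 1e5))
  expect_equal(sum(w$count), 10000L)
})

test_that("HF windows exceed the chromosome mean by the multiplier", {
  # chromosome of 10 Mb, 1 Mb windows: 12 mutations spread, one window with 7
  g <- genome_model(c(chr4 = 1e7))
  pos <- c(seq(5e5, 9.5e6, by = 2e6),     # 5 scattered
           seq(3.1e6, 3.9e6, by = 1.5e5)) # 6 clustered in window 4
  w <- window_counts(mut_pos(pos, chrom = "chr4"), g, 1e6)
  regions <- detect_hf_lf(w, hf_multiplier = 4)
  hf <- regions[regions$label == "HF", ]
  expect_equal(nrow(hf), 1)
  expect_equal(hf$start, 3e6 + 1)
  expect_true(hf$frequency >= 4 * hf$chromosome_mean_frequency)
  lf <- regions[regions$label == "LF", ]
  expect_true(all(lf$count == 0))
  # homogeneous profile yields neither HF nor LF
  g2 <- genome_model(c(chr1 = 4e6))
  w2 <- window_counts(mut_pos(rep(seq(1e5, 3.9e6, by = 2e5), 2)), g2, 1e6)
  expect_equal(nrow(detect_hf_lf(w2, hf_multiplier = 4)), 0)
})

test_that("HF/LF detection is scale-free", {
  set.seed(5)
  pos <- c(sample.int(1e6, 30), sample(200001:220000, 20, replace = FALSE))
  g1 <- genome_model(c(chr1 = 1e6))
  r1 <- detect_hf_lf(window_counts(mut_pos(pos), g1, 5e4))
  g10 <- genome_model(c(chr1 = 1e7))
  r10 <- detect_hf_lf(window_counts(mut_pos(pos * 10 - 9), g10, 5e5))
  expect_equal(r1$label, r10$label)
  expect_equal(r1$count, r10$count)
})

test_that("HF regions test significantly above LF regions", {
  hf <- data.frame(frequency = c(5, 6, 7) * 1e-6)
  lf <- data.frame(frequency = c(0, 0, 0))
  r <- compare_hf_lf(hf, lf)
  expect_lt(r$p.value, 0.05)
  same <- data.frame(frequency = c(1, 1, 1) * 1e-6)
  expect_equal(compare_hf_lf(same, same)$p.value, 1)
  expect_error(compare_hf_lf(hf[1, , drop = FALSE], lf), "at least two")
  # Welch statistic agrees with the closed form on a hand-built 3+3 example
  x <- c(2, 4, 6); y <- c(1, 1, 2)
  got <- compare_hf_lf(data.frame(frequency = x), data.frame(frequency = y))
  tstat <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(got$statistic, tstat)
})

test_that("common HF regions are interval intersections across treatments", {
  cib <- data.frame(chrom = "chr9", start = 8e6 + 1, end = 9e6)
  gr <- data.frame(chrom = "chr9", start = 8e6 + 1, end = 9e6)
  common <- common_hf_regions(list(CIB = cib, GR = gr))
  expect_equal(common$start, 8e6 + 1)
  expect_equal(common$end, 9e6)
  disjoint <- common_hf_regions(list(
    A = data.frame(chrom = "chr1", start = 1, end = 100),
    B = data.frame(chrom = "chr1", start = 200, end = 300)))
  expect_equal(nrow(disjoint), 0)
  # random interval sets match the brute-force pairwise intersection
  set.seed(7)
  rand_regions <- function(n) {
    s <- sort(sample.int(1e6, n))
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = s, end = s + sample.int(5e4, n),
               stringsAsFactors = FALSE)
  }
  for (i in 1:20) {
    a <- rand_regions(6); b <- rand_regions(6)
    # reduce overlaps within each set first so both routes see canonical input
    canon <- function(df) {
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start, df$end)))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
    }
    a <- canon(a); b <- canon(b)
    got <- common_hf_regions(list(a = a, b = b))
    want <- oracle_intersect(a, b)
    got <- got[order(got$chrom, got$start), , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("InDel-SBS proximity equals a brute-force all-pairs scan", {
  m <- rbind(
    data.frame(mtype = "InDel", chrom = "chr1", pos = 5000L),
    data.frame(mtype = "SBS", chrom = "chr1", pos = 9000L)
  )
  expect_equal(indel_sbs_proximity(m, 1e4)$fraction, 1)
  m2 <- data.frame(mtype = "InDel", chrom = "chr1", pos = 5000L)
  expect_equal(indel_sbs_proximity(m2, 1e4)$fraction, 0)
  set.seed(55)
  big <- data.frame(
    mtype = sample(c("InDel", "SBS", "MNV"), 1000, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample.int(2e6, 1000), stringsAsFactors = FALSE)
  r <- indel_sbs_proximity(big, 1e4)
  manual <- 0
  ind <- big[big$mtype == "InDel", ]
  sbs <- big[big$mtype == "SBS", ]
  for (i in seq_len(nrow(ind))) {
    hit <- FALSE
    for (j in seq_len(nrow(sbs))) {
      if (ind$chrom[i] == sbs$chrom[j] &&
          abs(ind$pos[i] - sbs$pos[j]) <= 1e4) hit <- TRUE
    }
    manual <- manual + hit
  }
  expect_equal(r$n_accompanied, manual)
  expect_equal(r$fraction, manual / nrow(ind))
  sens <- proximity_sensitivity(big)
  expect_true(all(diff(sens$fraction) >= 0))
})

test_that("window totals conserve the mutation count", {
  sim <- simulate_cohort(test_config())
  res <- run_pipeline(sim$vcf_path, sim$genome)
  w <- window_counts(res$mutations, sim$genome, 5e4)
  f <- chromosome_frequency(res$mutations, sim$genome)
  expect_equal(sum(w$count), nrow(res$mutations))
  expect_equal(sum(f$count), nrow(res$mutations))
  per_chrom_w <- tapply(w$count, w$chrom, sum)
  expect_equal(as.integer(per_chrom_w[f$chrom]), f$count)
})
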