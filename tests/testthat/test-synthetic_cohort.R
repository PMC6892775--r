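test_that("genome simulation is deterministic and genes are well-separated", {
  cfg <- test_config()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  fa1 <- tempfile(); fa2 <- tempfile()
  write_fasta(a$genome, fa1); write_fasta(b$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  gf1 <- tempfile(); gf2 <- tempfile()
  write_gff(a$genes, gf1); write_gff(b$genes, gf2)
  expect_identical(readLines(gf1), readLines(gf2))
  # non-overlapping genes with free flanks
  for (ch in unique(vapply(a$genes, `[[`, "", "chrom"))) {
    gs <- Filter(function(g) g$chrom == ch, a$genes)
    bounds <- t(vapply(gs, function(g) c(g$tx_start, g$tx_end), numeric(2)))
    bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
    if (nrow(bounds) > 1) {
      gaps <- bounds[-1, 1] - bounds[-nrow(bounds), 2]
      expect_true(all(gaps >= 2 * 5000))
    }
  }
})

test_that("simulated sequence composition is near-uniform", {
  cfg <- cohort_config(chrom_lengths = c(chr1 = 1e6), genes_per_chrom = 0,
                       seed = 5)
  sim <- simulate_genome(cfg)
  gc <- sum(strsplit(sim$genome$sequence[["chr1"]], "")[[1]] %in%
              c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("degenerate type mix produces only that type", {
  cfg <- test_config(type_mix = c(SBS = 1, MNV = 0, InDel = 0, SV = 0),
                     n_background = 0)
  sim <- simulate_genome(cfg)
  truth <- simulate_line_mutations(cfg, sim$genome)
  expect_true(all(truth$mutations$mtype == "SBS"))
  expect_true(all(nchar(truth$mutations$ref) == 1 &
                    nchar(truth$mutations$alt) == 1))
})

test_that("realized Ti/Tv of SBS draws matches the configured ratio", {
  cfg <- cohort_config(
    n_lines = 4, chrom_lengths = c(chr1 = 1.5e6, chr2 = 1.5e6),
    per_line_mutation_count = 2500, genes_per_chrom = 0,
    type_mix = c(SBS = 1, MNV = 0, InDel = 0, SV = 0),
    titv_ratio = 2.0, n_background = 0, seed = 21
  )
  sim <- simulate_genome(cfg)
  truth <- simulate_line_mutations(cfg, sim$genome)
  spec <- substitution_spectrum(truth$mutations)
  tt <- titv_ratio(spec)
  expect_gt(tt$n_transitions + tt$n_transversions, 9000)
  expect_lt(abs(tt$titv - 2.0), 0.1)
})

test_that("hotspot windows receive the expected share of mutations", {
  hs <- data.frame(chrom = "chr1", start = 300001L, end = 310000L,
                   rate_multiplier = 10)
  cfg <- cohort_config(
    n_lines = 4, chrom_lengths = c(chr1 = 1e6), genes_per_chrom = 0,
    per_line_mutation_count = 500,
    type_mix = c(SBS = 1, MNV = 0, InDel = 0, SV = 0),
    hotspot_windows = hs, n_background = 0, seed = 31
  )
  sim <- simulate_genome(cfg)
  truth <- simulate_line_mutations(cfg, sim$genome)
  inside <- truth$mutations$pos >= 300001 & truth$mutations$pos <= 310000
  # expected fraction 10 * 0.01 / (0.99 + 10 * 0.01) = 0.0917
  expect_lt(abs(mean(inside) - 10 * 0.01 / (0.99 + 0.1)), 0.025)

  bad <- data.frame(chrom = "chr1", start = 999999L, end = 2e6,
                    rate_multiplier = 10)
  cfg_bad <- cohort_config(chrom_lengths = c(chr1 = 1e6),
                           hotspot_windows = bad, genes_per_chrom = 0)
  sim2 <- simulate_genome(cfg_bad)
  expect_error(simulate_line_mutations(cfg_bad, sim2$genome),
               "hotspot window outside genome")
})

test_that("lost mutations are kept in truth but never emitted", {
  cfg <- test_config(generations = 6)
  sim <- simulate_cohort(cfg)
  lost <- sim$truth$mutations[sim$truth$mutations$fate == "lost", ]
  expect_gt(nrow(lost), 0)
  expect_true(all(is.na(lost$zygosity)))
  lines <- readLines(sim$vcf_path)
  body <- lines[!startsWith(lines, "#")]
  pos_in_vcf <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  chrom_in_vcf <- vapply(strsplit(body, "\t"), `[`, "", 1)
  expect_false(any(paste(lost$chrom, lost$pos) %in%
                     paste(chrom_in_vcf, pos_in_vcf)))
})

test_that("emitted read support is binomial around the true allele fraction", {
  # a hand-built truth of purely heterozygous sites
  cfg <- cohort_config(n_lines = 1, chrom_lengths = c(chr1 = 2e6),
                       genes_per_chrom = 0, per_line_mutation_count = 2000,
                       type_mix = c(SBS = 1, MNV = 0, InDel = 0, SV = 0),
                       n_background = 0, seed = 41, mean_depth = 30)
  sim <- simulate_genome(cfg)
  truth <- simulate_line_mutations(cfg, sim$genome)
  truth$mutations$fate <- "het"
  truth$mutations$zygosity <- "heterozygous"
  path <- tempfile(fileext = ".vcf")
  emit_cohort_vcf(truth, sim$genome, path)
  cohort <- read_vcf_cohort(path, "WT")
  calls <- cohort$calls[cohort$calls$sample_id == "L01", ]
  vaf <- calls$alt_depth / (calls$ref_depth + calls$alt_depth)
  expect_gt(nrow(calls), 1900)
  expect_lt(abs(mean(vaf) - 0.5), 0.02)
  # homozygous carrier: alt depth equals total depth (p = 1)
  truth$mutations$fate <- "hom"
  truth$mutations$zygosity <- "homozygous"
  emit_cohort_vcf(truth, sim$genome, path)
  cohort <- read_vcf_cohort(path, "WT")
  calls <- cohort$calls[cohort$calls$sample_id == "L01", ]
  expect_true(all(calls$ref_depth == 0))

  expect_identical(emit_and_read(truth, sim$genome),
                   emit_and_read(truth, sim$genome))
})


test_that("background variants appear in every sample including wild type", {
  sim <- simulate_cohort(test_config())
  cohort <- read_vcf_cohort(sim$vcf_path, "WT")
  bg <- sim$truth$background
  for (i in seq_len(nrow(bg))) {
    carriers <- cohort$calls$sample_id[cohort$calls$chrom == bg$chrom[i] &
                                         cohort$calls$pos == bg$pos[i]]
    expect_setequal(carriers, cohort$samples)
  }
  # wild type carries nothing else
  wt_calls <- cohort$calls[cohort$calls$sample_id == "WT", ]
  expect_true(all(paste(wt_calls$chrom, wt_calls$pos) %in%
                    paste(bg$chrom, bg$pos)))
})
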