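# Hand-built two-exon coding gene on a known sequence for exact-effect tests.
# Layout (chr1, + strand): 5kb flank | UTR5 | CDS exon1 | intron | CDS exon2 |
# UTR3. CDS is ATG TGG GGA CCT ... TAA with known codons.
build_effect_fixture <- function(strand = "+") {
  set.seed(314)
  flank <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                 collapse = "")
  utr5 <- strrep("A", 12)
  cds1 <- "ATGTGGGGACCT"          # M W G P
  intron <- paste0("GT", strrep("C", 96), "AG")
  cds2 <- "GAATACAAGTAA"          # E Y K *
  utr3 <- strrep("T", 12)
  seq <- paste0(flank, utr5, cds1, intron, cds2, utr3, flank)
  tx_start <- 6001L
  e1s <- tx_start
  e1e <- tx_start + 12L + 12L - 1L            # utr5 + cds1
  e2s <- e1e + 100L + 1L                       # after intron
  e2e <- e2s + 12L + 12L - 1L                  # cds2 + utr3
  cds_start <- tx_start + 12L
  cds_end <- e2s + 11L
  if (strand == "-") {
    # mirror the whole construct by reverse complement
    n <- nchar(seq)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    flip <- function(p) n - p + 1L
    # exons: [flip(e2e), flip(e2s)] and [flip(e1e), flip(e1s)]
    g <- gene_model("g1", "chr1", "-",
                    flip(e2e), flip(e1s),
                    rbind(c(flip(e2e), flip(e2s)), c(flip(e1e), flip(e1s))),
                    cds_start = flip(cds_end), cds_end = flip(cds_start))
    return(list(genome = make_test_genome(rc), gene = g,
                coord = function(p) flip(p)))
  }
  g <- gene_model("g1", "chr1", "+", tx_start, e2e,
                  rbind(c(e1s, e1e), c(e2s, e2e)),
                  cds_start = cds_start, cds_end = cds_end)
  list(genome = make_test_genome(seq), gene = g, coord = identity,
       cds_start = cds_start, e1s = e1s, e1e = e1e, e2s = e2s, e2e = e2e,
       tx_start = tx_start)
}

ann_mut <- function(pos, ref, alt, chrom = "chr1") {
  data.frame(line_id = "L1", chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = alt, length = nchar(alt) - nchar(ref),
             mtype = if (nchar(ref) == nchar(alt)) {
               if (nchar(ref) == 1) "SBS" else "MNV"
             } else "InDel",
             stringsAsFactors = FALSE)
}

test_that("feature assignment follows strand-aware precedence", {
  fx <- build_effect_fixture()
  g <- list(fx$gene)
  cfg <- annotation_config()
  feat <- function(p) assign_feature(ann_mut(p, "A", "G"), g, cfg)$feature
  expect_equal(feat(fx$cds_start + 2), "exon")
  expect_equal(feat(fx$tx_start + 3), "UTR5")
  expect_equal(feat(fx$e2e - 3), "UTR3")
  expect_equal(feat(fx$e1e + 1), "splice_region")
  expect_equal(feat(fx$e1e + 2), "splice_region")
  expect_equal(feat(fx$e1e + 3), "intron")
  expect_equal(feat(fx$tx_start - 3000), "upstream")
  expect_equal(feat(fx$tx_start - 5001), "intergenic")
  expect_equal(feat(fx$e2e + 100), "downstream")
})

test_that("feature assignment equals a brute-force scan on random positions", {
  sim <- simulate_genome(test_config())
  set.seed(17)
  n <- 3000
  chrom <- sample(sim$genome$chromosomes$name, n, replace = TRUE,
                  prob = sim$genome$chromosomes$length)
  pos <- vapply(chrom, function(ch) {
    sample.int(sim$genome$chromosomes$length[
      sim$genome$chromosomes$name == ch], 1)
  }, integer(1))
  tbl <- data.frame(line_id = "L1", chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  got <- assign_feature(tbl, sim$genes)
  want <- vapply(seq_len(n), function(i) {
    oracle_feature(pos[i], chrom[i], sim$genes)
  }, character(1))
  expect_equal(got$feature, want)
})

test_that("coding substitutions are classified by codon replacement", {
  fx <- build_effect_fixture()
  # third position of Gly codon GGA -> GGG: silent
  p_gly3 <- fx$cds_start + 8L
  r <- predict_effect(ann_mut(p_gly3, "A", "G"), fx$gene, fx$genome)
  expect_equal(r$effect, "silent")
  # TGG (Trp) -> TGA: nonsense, functionally affected
  p_trp3 <- fx$cds_start + 5L
  r <- predict_effect(ann_mut(p_trp3, "G", "A"), fx$gene, fx$genome)
  expect_equal(r$effect, "nonsense")
  expect_true(r$functionally_affected)
  # terminal TAA -> CAA: stop lost
  p_stop1 <- fx$e2s + 9L
  r <- predict_effect(ann_mut(p_stop1, "T", "C"), fx$gene, fx$genome)
  expect_equal(r$effect, "stop_lost")
  expect_true(r$functionally_affected)
  # GAA (Glu) -> AAA (Lys): missense
  r <- predict_effect(ann_mut(fx$e2s, "G", "A"), fx$gene, fx$genome)
  expect_equal(r$effect, "missense")
  expect_false(r$functionally_affected)
})

test_that("an MNV spanning a codon boundary is evaluated jointly", {
  fx <- build_effect_fixture()
  # bases 3-4 of CDS: G of ATG and T of TGG changed together
  p <- fx$cds_start + 2L
  r <- predict_effect(ann_mut(p, "GT", "TA"), fx$gene, fx$genome)
  # ATG TGG -> ATT AGG : M->I, W->R, no stop: missense
  expect_equal(r$effect, "missense")
})

test_that("CDS indels are frameshift/inframe with premature-stop detection", {
  fx <- build_effect_fixture()
  # 8-bp deletion in the first coding exon: frameshift, premature stop
  p <- fx$cds_start
  ref8 <- substr(fx$genome$sequence[[1]], p, p + 8L)
  r <- predict_effect(ann_mut(p, ref8, substr(ref8, 1, 1)),
                      fx$gene, fx$genome)
  expect_equal(r$effect, "frameshift")
  expect_true(r$functionally_affected)
  # 3-bp deletion: inframe
  ref3 <- substr(fx$genome$sequence[[1]], p, p + 3L)
  r <- predict_effect(ann_mut(p, ref3, substr(ref3, 1, 1)),
                      fx$gene, fx$genome)
  expect_equal(r$effect, "inframe_indel")
  expect_false(r$functionally_affected)
})

test_that("minus-strand genes are evaluated on the coding strand", {
  fx <- build_effect_fixture("-")
  # the Trp codon TGG: on the reference strand this gene region is reverse
  # complemented, so the same biological edit is a C>T on the genome
  plus <- build_effect_fixture()
  p_plus <- plus$cds_start + 5L
  p_minus <- fx$coord(p_plus)
  r <- predict_effect(ann_mut(p_minus, "C", "T"), fx$gene, fx$genome)
  expect_equal(r$effect, "nonsense")
  # and a silent wobble change mirrors too
  p_minus2 <- fx$coord(plus$cds_start + 8L)
  r2 <- predict_effect(ann_mut(p_minus2, "T", "C"), fx$gene, fx$genome)
  expect_equal(r2$effect, "silent")
})

test_that("predict_effect agrees with whole-CDS retranslation", {
  sim <- simulate_genome(test_config())
  coding <- Filter(radmut:::is_coding, sim$genes)
  set.seed(29)
  n_checked <- 0
  for (i in 1:300) {
    gene <- coding[[sample.int(length(coding), 1)]]
    info <- radmut:::cds_sequence(gene, sim$genome)
    seq <- sim$genome$sequence[[gene$chrom]]
    if (runif(1) < 0.6) {
      # random coding SBS
      gp <- sample(info$coords, 1)
      ref <- substr(seq, gp, gp)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      m <- ann_mut(gp, ref, alt)
    } else {
      # random small indel fully inside one exon's coding part
      ex <- gene$exons[sample.int(nrow(gene$exons), 1), ]
      cs <- max(ex[1], gene$cds_start)
      ce <- min(ex[2], gene$cds_end)
      if (ce - cs < 30) next
      gp <- sample(seq.int(cs + 2, ce - 15), 1)
      k <- sample.int(10, 1)
      if (runif(1) < 0.7) {
        ref <- substr(seq, gp, gp + k)
        m <- ann_mut(gp, ref, substr(ref, 1, 1))
      } else {
        ref <- substr(seq, gp, gp)
        m <- ann_mut(gp, ref, paste0(ref, paste(
          sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")))
      }
    }
    got <- predict_effect(m, gene, sim$genome)
    want <- oracle_effect(m, gene, sim$genome)
    expect_equal(got$effect, want$effect)
    expect_equal(got$functionally_affected, want$functionally_affected)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("effect summary computes shares from counts", {
  ann <- data.frame(
    line_id = "H633",
    mtype = "SBS", feature = "exon",
    effect = c(rep("missense", 25), rep("silent", 18)),
    functionally_affected = FALSE,
    gene_id = "g", stringsAsFactors = FALSE
  )
  s <- effect_summary(ann)
  silent <- s$effect_counts[s$effect_counts$effect == "silent", ]
  expect_equal(silent$count, 18L)
  expect_equal(silent$percent, 41.86)
  # empty input: no division by zero
  empty <- ann[0, ]
  s0 <- effect_summary(empty)
  expect_true(all(s0$effect_counts$count == 0 | is.na(s0$effect_counts$count)))
})

test_that("region distribution percentages sum to 100 per class", {
  ann <- data.frame(
    line_id = "L1", mtype = rep(c("SBS", "InDel"), c(4, 2)),
    feature = c("upstream", "upstream", "exon", "exon", "intron", "exon"),
    stringsAsFactors = FALSE
  )
  d <- region_distribution(ann)
  sbs <- d[d$mtype == "SBS", ]
  expect_equal(sbs$percent[sbs$feature == "upstream"], 50)
  expect_equal(sbs$percent[sbs$feature == "exon"], 50)
  for (cl in unique(d$mtype)) {
    expect_lt(abs(sum(d$percent[d$mtype == cl]) - 100), 0.05)
  }
})

test_that("functionally affected genes are recovered from injected variants", {
  sim <- simulate_genome(test_config())
  coding <- Filter(radmut:::is_coding, sim$genes)
  gene <- coding[[1]]
  seq <- sim$genome$sequence[[gene$chrom]]
  # inject a guaranteed stop-gain: find a coding position whose substitution
  # creates a stop (scan candidate positions with the oracle)
  info <- radmut:::cds_sequence(gene, sim$genome)
  found <- NULL
  for (gp in info$coords) {
    ref <- substr(seq, gp, gp)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      if (oracle_effect(ann_mut(gp, ref, alt), gene,
                        sim$genome)$effect == "nonsense") {
        found <- ann_mut(gp, ref, alt)
        break
      }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  ann <- annotate_mutations(found, sim$genes, sim$genome)
  expect_equal(ann$effect, "nonsense")
  s <- effect_summary(ann)
  expect_equal(s$affected_genes$gene_ids, gene$gene_id)
})
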