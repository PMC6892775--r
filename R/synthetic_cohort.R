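#' Configuration for the synthetic mutant cohort generator
#'
#' The generator emulates the statistical structure of a re-sequenced selfed
#' mutant cohort: line-private induced mutations drawn from a configurable
#' type mix, a transition-biased substitution spectrum, deletion-heavy InDel
#' sizes, consecutive-base MNVs, optional clustered high-frequency windows,
#' shared background variants present in every sample, binomially sampled
#' read support around the true allele frequency, and zygosity states from
#' `generations` rounds of selfing.
#'
#' Defaults follow the carbon-ion-beam arm of the study the pipeline targets:
#' 6 lines, type mix 175:36:72 SBS:MNV:InDel (no SVs), Ti/Tv 2.22, 83.1%
#' deletions among InDels, ~30x depth, sequencing at generation 4.
#'
#' @param n_lines number of mutant lines (wild type added automatically).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param per_line_mutation_count Poisson mean of induced mutations per line.
#' @param type_mix proportions over SBS, MNV, InDel, SV (normalized).
#' @param titv_ratio expected transition/transversion ratio of SBS draws.
#' @param indel_deletion_fraction probability an InDel is a deletion.
#' @param indel_length_distribution probabilities over lengths 1..10 bp.
#' @param mnv_length_distribution probabilities over run lengths 2..5 bp.
#' @param hotspot_windows optional data.frame `chrom, start, end,
#'   rate_multiplier` of mutation-rate hotspots.
#' @param n_background shared background variants present in every sample.
#' @param generations selfing generation at sequencing (g >= 2).
#' @param mean_depth Poisson mean of per-sample read depth.
#' @param genes_per_chrom gene models tiled per chromosome.
#' @param seed RNG seed; every generator stage is deterministic given it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_lines = 6,
                          chrom_lengths = c(chr1 = 1e6, chr2 = 8e5,
                                            chr3 = 6e5),
                          per_line_mutation_count = 100,
                          type_mix = c(SBS = 175, MNV = 36, InDel = 72,
                                       SV = 0),
                          titv_ratio = 2.22,
                          indel_deletion_fraction = 0.831,
                          indel_length_distribution =
                            c(0.30, 0.20, 0.13, 0.09, 0.08,
                              0.06, 0.05, 0.04, 0.03, 0.02),
                          mnv_length_distribution = c(0.70, 0.20, 0.07, 0.03),
                          hotspot_windows = NULL,
                          n_background = 50,
                          generations = 4,
                          mean_depth = 30,
                          genes_per_chrom = 5,
                          seed = 1) {
  stopifnot(n_lines >= 1, all(chrom_lengths > 0),
            per_line_mutation_count > 0, titv_ratio > 0,
            indel_deletion_fraction >= 0, indel_deletion_fraction <= 1,
            length(indel_length_distribution) == 10,
            length(mnv_length_distribution) == 4,
            generations >= 2, mean_depth > 0)
  type_mix <- type_mix / sum(type_mix)
  stopifnot(setequal(names(type_mix), c("SBS", "MNV", "InDel", "SV")))
  if (!is.null(hotspot_windows)) {
    stopifnot(all(c("chrom", "start", "end", "rate_multiplier") %in%
                    names(hotspot_windows)))
  }
  structure(list(
    n_lines = as.integer(n_lines), chrom_lengths = chrom_lengths,
    per_line_mutation_count = per_line_mutation_count,
    type_mix = type_mix[c("SBS", "MNV", "InDel", "SV")],
    titv_ratio = titv_ratio,
    indel_deletion_fraction = indel_deletion_fraction,
    indel_length_distribution =
      indel_length_distribution / sum(indel_length_distribution),
    mnv_length_distribution =
      mnv_length_distribution / sum(mnv_length_distribution),
    hotspot_windows = hotspot_windows,
    n_background = as.integer(n_background),
    generations = as.integer(generations),
    mean_depth = mean_depth,
    genes_per_chrom = as.integer(genes_per_chrom),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

line_ids <- function(config) sprintf("L%02d", seq_len(config$n_lines))

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

NON_STOP_CODONS <- {
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Build one gene layout inside [slot_start, slot_end]; returns the gene model
# and the coding-strand CDS string to be written into the chromosome.
random_gene <- function(gene_id, chrom, slot_start, slot_end) {
  strand <- sample(c("+", "-"), 1)
  n_exons <- sample(1:3, 1)
  coding_lens <- sample(seq(90, 300, by = 3), n_exons, replace = TRUE)
  utr_left <- sample(30:60, 1)
  utr_right <- sample(30:60, 1)
  intron_lens <- if (n_exons > 1) sample(80:200, n_exons - 1, replace = TRUE)
                 else integer(0)
  exon_lens <- coding_lens
  exon_lens[1] <- exon_lens[1] + utr_left
  exon_lens[n_exons] <- exon_lens[n_exons] + utr_right
  total <- sum(exon_lens) + sum(intron_lens)
  if (slot_end - slot_start + 1 < total) {
    stop("chromosome segment too small for gene ", gene_id)
  }
  tx_start <- slot_start + sample.int(slot_end - slot_start + 2 - total, 1) - 1L
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  cur <- tx_start
  for (i in seq_len(n_exons)) {
    starts[i] <- cur
    ends[i] <- cur + exon_lens[i] - 1L
    cur <- ends[i] + 1L + if (i < n_exons) intron_lens[i] else 0L
  }
  cds_start <- starts[1] + utr_left
  cds_end <- ends[n_exons] - utr_right
  cds_len <- sum(coding_lens)
  n_codons <- cds_len / 3
  cds <- paste0("ATG",
                paste(sample(NON_STOP_CODONS, n_codons - 2, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1))
  list(
    gene = gene_model(gene_id, chrom, strand, tx_start, ends[n_exons],
                      cbind(starts, ends), cds_start, cds_end),
    cds = cds
  )
}

#' Simulate a toy genome with tiled gene models
#'
#' Chromosomes are uniform-random DNA; genes are tiled in equal slots with
#' flanks of at least 10 kb free of neighboring genes so that feature
#' assignment is unambiguous. Each gene carries a clean reading frame (ATG,
#' stop-free body, terminal stop) spliced across 1–3 exons on a random strand.
#'
#' @param config a [cohort_config()].
#' @return list with `genome` (a [genome_model()] with sequence) and `genes`
#'   (list of [gene_model()]).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  flank_gap <- 10000L
  genes <- list()
  sequence <- character(length(config$chrom_lengths))
  names(sequence) <- names(config$chrom_lengths)
  for (ci in seq_along(config$chrom_lengths)) {
    ch <- names(config$chrom_lengths)[ci]
    len <- as.integer(config$chrom_lengths[ci])
    bases <- sample(DNA_BASES, len, replace = TRUE)
    n_genes <- config$genes_per_chrom
    if (n_genes > 0) {
      slot <- len %/% n_genes
      if (slot < 2L * flank_gap + 2000L) {
        stop("chromosome ", ch, " too small for ", n_genes, " genes")
      }
      for (gi in seq_len(n_genes)) {
        slot_start <- (gi - 1L) * slot + flank_gap + 1L
        slot_end <- gi * slot - flank_gap
        rg <- random_gene(sprintf("%s.g%d", ch, gi), ch, slot_start, slot_end)
        g <- rg$gene
        cds <- rg$cds
        if (g$strand == "-") cds <- rev_comp(cds)
        # write coding bases into the chromosome, exon by exon
        offset <- 0L
        for (i in seq_len(nrow(g$exons))) {
          cs <- max(g$exons[i, "start"], g$cds_start)
          ce <- min(g$exons[i, "end"], g$cds_end)
          if (cs <= ce) {
            seg_len <- ce - cs + 1L
            bases[cs:ce] <- strsplit(substr(cds, offset + 1L,
                                            offset + seg_len), "")[[1]]
            offset <- offset + seg_len
          }
        }
        genes[[length(genes) + 1]] <- g
      }
    }
    sequence[ch] <- paste(bases, collapse = "")
  }
  genome <- genome_model(
    data.frame(name = names(config$chrom_lengths),
               length = as.integer(config$chrom_lengths),
               stringsAsFactors = FALSE),
    sequence = sequence
  )
  list(genome = genome, genes = genes)
}

# Sample mutation positions: uniform over the genome except inside hotspot
# windows, whose rate is scaled by their multiplier (rejection sampling).
# Positions keep `min_gap` bp from previously used positions and from
# chromosome ends.
sample_positions <- function(n, genome, hotspots, used_env, min_gap = 15L) {
  lens <- genome$chromosomes$length
  names(lens) <- genome$chromosomes$name
  if (!is.null(hotspots)) {
    check_contigs(hotspots$chrom, genome)
    if (any(hotspots$end > lens[hotspots$chrom] | hotspots$start < 1)) {
      stop("hotspot window outside genome")
    }
    max_mult <- max(1, hotspots$rate_multiplier)
  } else {
    max_mult <- 1
  }
  out_chrom <- character(n)
  out_pos <- integer(n)
  filled <- 0L
  guard <- 0L
  while (filled < n) {
    guard <- guard + 1L
    if (guard > 200000L) stop("could not place mutations; genome too dense")
    ch <- sample(names(lens), 1, prob = lens)
    pos <- sample.int(lens[[ch]] - 2L * min_gap, 1) + min_gap
    mult <- 1
    if (!is.null(hotspots)) {
      hit <- hotspots$chrom == ch & hotspots$start <= pos & hotspots$end >= pos
      if (any(hit)) mult <- max(hotspots$rate_multiplier[hit])
    }
    if (runif(1) > mult / max_mult) next
    key <- ch
    prev <- used_env$pos[[key]]
    if (!is.null(prev) && any(abs(prev - pos) < min_gap)) next
    used_env$pos[[key]] <- c(prev, pos)
    filled <- filled + 1L
    out_chrom[filled] <- ch
    out_pos[filled] <- pos
  }
  data.frame(chrom = out_chrom, pos = out_pos, stringsAsFactors = FALSE)
}

draw_sbs <- function(ref, titv) {
  p_ti <- titv / (1 + titv)
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(ref, function(b) {
    if (runif(1) < p_ti) partner[[b]]
    else sample(setdiff(DNA_BASES, c(b, partner[[b]])), 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate line-private mutations with known truth
#'
#' Draws each line's mutation count from a Poisson, places mutations uniformly
#' (hotspot windows upweighted by their rate multiplier), draws the type from
#' the configured mix and the alleles from the configured spectra, and
#' assigns each mutation a selfing fate at generation `g` via
#' [simulate_selfing()]. Lost mutations stay in the truth table with fate
#' `"lost"` but are absent from any line's observable set.
#'
#' @param config a [cohort_config()].
#' @param genome a [genome_model()] with sequence from [simulate_genome()].
#' @return object of class `cohort_truth`: list with `mutations` (data.frame
#'   `line_id, chrom, pos, ref, alt, mtype, length, fate, zygosity`),
#'   `background` (data.frame `chrom, pos, ref, alt`) and `config`.
#' @export
simulate_line_mutations <- function(config, genome) {
  stopifnot(!is.null(genome$sequence))
  set.seed(config$seed + 1L)
  used <- new.env()
  used$pos <- list()
  # spacing keeps same-line substitutions from fusing into accidental MNVs
  # and keeps indel/SV spans clear of neighboring sites and chromosome ends
  min_gap <- if (config$type_mix[["SV"]] > 0) 110L else 15L
  lines <- line_ids(config)
  rows <- list()
  for (l in lines) {
    n <- stats::rpois(1, config$per_line_mutation_count)
    if (n == 0) next
    sites <- sample_positions(n, genome, config$hotspot_windows, used,
                              min_gap)
    mtype <- sample(names(config$type_mix), n, replace = TRUE,
                    prob = config$type_mix)
    ref <- character(n)
    alt <- character(n)
    for (i in seq_len(n)) {
      seq <- genome$sequence[[sites$chrom[i]]]
      p <- sites$pos[i]
      if (mtype[i] == "SBS") {
        ref[i] <- substr(seq, p, p)
        alt[i] <- draw_sbs(ref[i], config$titv_ratio)
      } else if (mtype[i] == "MNV") {
        k <- sample(2:5, 1, prob = config$mnv_length_distribution)
        ref[i] <- substr(seq, p, p + k - 1)
        alt[i] <- paste(vapply(strsplit(ref[i], "")[[1]], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1)), collapse = "")
      } else {
        k <- if (mtype[i] == "SV") sample(51:100, 1)
             else sample(1:10, 1, prob = config$indel_length_distribution)
        if (mtype[i] != "SV" && runif(1) >= config$indel_deletion_fraction) {
          ref[i] <- substr(seq, p, p)  # insertion
          alt[i] <- paste0(ref[i], random_dna(k))
        } else {
          ref[i] <- substr(seq, p, p + k)  # deletion (anchor + k bases)
          alt[i] <- substr(seq, p, p)
        }
        # store the canonical (left-aligned) representation in the truth so
        # recovery can be judged by exact identity
        tr <- left_align(p, ref[i], alt[i], seq)
        sites$pos[i] <- tr$pos
        ref[i] <- tr$ref
        alt[i] <- tr$alt
      }
    }
    fate <- simulate_selfing(n, config$generations)
    rows[[l]] <- data.frame(
      line_id = l, chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
      mtype = mtype, length = nchar(alt) - nchar(ref), fate = fate,
      zygosity = ifelse(fate == "hom", "homozygous",
                        ifelse(fate == "het", "heterozygous", NA_character_)),
      stringsAsFactors = FALSE
    )
  }
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL
  background <- NULL
  if (config$n_background > 0) {
    sites <- sample_positions(config$n_background, genome,
                              config$hotspot_windows, used, min_gap)
    ref <- vapply(seq_len(nrow(sites)), function(i) {
      substr(genome$sequence[[sites$chrom[i]]], sites$pos[i], sites$pos[i])
    }, character(1))
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1), USE.NAMES = FALSE)
    background <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                             alt = alt, stringsAsFactors = FALSE)
  } else {
    background <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             stringsAsFactors = FALSE)
  }
  structure(list(mutations = mutations, background = background,
                 config = config), class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("cohort_truth:", nrow(x$mutations), "line mutations (",
      sum(x$mutations$fate != "lost"), "observable ),",
      nrow(x$background), "background sites\n")
  invisible(x)
}

#' Emit a multi-sample VCF for a simulated cohort
#'
#' Per site and sample, total depth is Poisson(`mean_depth`) and alt depth is
#' Binomial(depth, p) with p = 1 for a homozygous carrier, 0.5 for a
#' heterozygous carrier and 0 for a non-carrier. Background variants are
#' homozygous in every sample including the wild type, which otherwise
#' carries nothing.
#'
#' @param truth a `cohort_truth` from [simulate_line_mutations()].
#' @param genome the matching [genome_model()].
#' @param path output VCF path.
#' @param wild_type_id sample name for the wild type column.
#' @return `path`, invisibly.
#' @export
emit_cohort_vcf <- function(truth, genome, path, wild_type_id = "WT") {
  config <- truth$config
  set.seed(config$seed + 2L)
  lines <- line_ids(config)
  samples <- c(lines, wild_type_id)
  obs <- truth$mutations[truth$mutations$fate != "lost", , drop = FALSE]
  site <- rbind(
    data.frame(chrom = obs$chrom, pos = obs$pos, ref = obs$ref,
               alt = obs$alt, carrier = obs$line_id,
               zygosity = obs$zygosity, stringsAsFactors = FALSE),
    if (nrow(truth$background)) {
      data.frame(chrom = truth$background$chrom, pos = truth$background$pos,
                 ref = truth$background$ref, alt = truth$background$alt,
                 carrier = "*", zygosity = "homozygous",
                 stringsAsFactors = FALSE)
    }
  )
  chrom_order <- match(site$chrom, genome$chromosomes$name)
  site <- site[order(chrom_order, site$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radmut_synthetic_cohort",
    sprintf("##contig=<ID=%s,length=%d>", genome$chromosomes$name,
            genome$chromosomes$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(site)), function(i) {
    cells <- vapply(samples, function(s) {
      carries <- site$carrier[i] == "*" || site$carrier[i] == s
      if (site$carrier[i] == "*") {
        p <- 1; gt <- "1/1"
      } else if (carries && site$zygosity[i] == "homozygous") {
        p <- 1; gt <- "1/1"
      } else if (carries) {
        p <- 0.5; gt <- "0/1"
      } else {
        p <- 0; gt <- "0/0"
      }
      depth <- stats::rpois(1, config$mean_depth)
      alt_d <- stats::rbinom(1, depth, p)
      sprintf("%s:%d,%d", gt, depth - alt_d, alt_d)
    }, character(1))
    paste(c(site$chrom[i], site$pos[i], ".", site$ref[i], site$alt[i], ".",
            "PASS", ".", "GT:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a full synthetic cohort (genome, genes, truth, VCF)
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, writes `genome.fasta`,
#'   `genes.gff3`, `cohort.vcf` and `truth.tsv` there.
#' @param wild_type_id wild-type sample name.
#' @return list with `genome`, `genes`, `truth`, `vcf_path` (NULL when no
#'   `out_dir` and no `vcf` requested) and `wild_type_id`.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL,
                            wild_type_id = "WT") {
  sim <- simulate_genome(config)
  truth <- simulate_line_mutations(config, sim$genome)
  vcf_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
    write_gff(sim$genes, file.path(out_dir, "genes.gff3"))
    vcf_path <- file.path(out_dir, "cohort.vcf")
    emit_cohort_vcf(truth, sim$genome, vcf_path, wild_type_id)
    utils::write.table(truth$mutations, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    vcf_path <- tempfile(fileext = ".vcf")
    emit_cohort_vcf(truth, sim$genome, vcf_path, wild_type_id)
  }
  list(genome = sim$genome, genes = sim$genes, truth = truth,
       vcf_path = vcf_path, wild_type_id = wild_type_id)
}
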