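FEATURE_LEVELS <- c("exon", "splice_region", "UTR5", "UTR3", "intron",
                    "upstream", "downstream", "intergenic")

#' Annotation configuration
#'
#' @param upstream_bp,downstream_bp promoter/terminator window sizes measured
#'   from the transcript bounds, strand-aware (5 kb default, the common
#'   annotator convention).
#' @param splice_bp intronic bases adjacent to an exon boundary counted as
#'   splice region (default 2).
#' @return object of class `annotation_config`.
#' @export
annotation_config <- function(upstream_bp = 5000L, downstream_bp = 5000L,
                              splice_bp = 2L) {
  stopifnot(upstream_bp > 0, downstream_bp > 0, splice_bp > 0)
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp),
                 splice_bp = as.integer(splice_bp)),
            class = "annotation_config")
}

# Feature of positions relative to ONE gene; NA when outside all categories.
# "exon" means exonic AND inside the CDS interval; exonic positions outside
# the CDS are UTRs (5'/3' by strand). Splice region = first `splice_bp`
# intronic bases flanking an exon.
gene_feature <- function(pos, gene, config) {
  n <- length(pos)
  feat <- rep(NA_character_, n)
  ex <- gene$exons
  in_tx <- pos >= gene$tx_start & pos <= gene$tx_end
  in_exon <- rep(FALSE, n)
  for (i in seq_len(nrow(ex))) {
    in_exon <- in_exon | (pos >= ex[i, "start"] & pos <= ex[i, "end"])
  }
  in_intron <- in_tx & !in_exon
  # splice region: intronic bases within splice_bp of an exon boundary
  splice <- rep(FALSE, n)
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      intron_start <- ex[i, "end"] + 1L
      intron_end <- ex[i + 1, "start"] - 1L
      near <- (pos >= intron_start &
                 pos <= min(intron_start + config$splice_bp - 1L, intron_end)) |
              (pos <= intron_end &
                 pos >= max(intron_end - config$splice_bp + 1L, intron_start))
      splice <- splice | near
    }
  }
  if (is_coding(gene)) {
    in_cds <- in_exon & pos >= gene$cds_start & pos <= gene$cds_end
    utr_left <- in_exon & pos < gene$cds_start
    utr_right <- in_exon & pos > gene$cds_end
    if (gene$strand == "+") {
      utr5 <- utr_left; utr3 <- utr_right
    } else {
      utr5 <- utr_right; utr3 <- utr_left
    }
    feat[utr3] <- "UTR3"
    feat[utr5] <- "UTR5"
    feat[in_cds] <- "exon"
    feat[in_exon & is.na(feat)] <- if (gene$strand == "+") "UTR5" else "UTR3"
  } else {
    feat[in_exon] <- "exon"
  }
  feat[in_intron & splice] <- "splice_region"
  feat[in_intron & !splice] <- "intron"
  # upstream/downstream, strand-aware, outside the transcript
  if (gene$strand == "+") {
    up <- pos < gene$tx_start & pos >= gene$tx_start - config$upstream_bp
    down <- pos > gene$tx_end & pos <= gene$tx_end + config$downstream_bp
  } else {
    up <- pos > gene$tx_end & pos <= gene$tx_end + config$upstream_bp
    down <- pos < gene$tx_start & pos >= gene$tx_start - config$downstream_bp
  }
  feat[is.na(feat) & up] <- "upstream"
  feat[is.na(feat) & down] <- "downstream"
  feat
}

#' Assign a genomic feature to each mutation
#'
#' Each mutation position is tested against every gene model on its
#' chromosome; when several categories apply (overlapping genes or flanks)
#' the highest-precedence one wins: exon > splice_region > UTR5 > UTR3 >
#' intron > upstream > downstream > intergenic.
#'
#' @param mutations mutation data.frame (`chrom, pos`, other columns kept).
#' @param genes list of [gene_model()] objects.
#' @param config an [annotation_config()].
#' @return the data.frame with `feature` and `gene_id` columns (`gene_id` is
#'   `NA` for intergenic positions).
#' @export
assign_feature <- function(mutations, genes, config = annotation_config()) {
  n <- nrow(mutations)
  best <- rep(length(FEATURE_LEVELS), n)  # intergenic
  gene_id <- rep(NA_character_, n)
  for (g in genes) {
    on_chrom <- which(mutations$chrom == g$chrom)
    if (length(on_chrom) == 0) next
    feat <- gene_feature(mutations$pos[on_chrom], g, config)
    rank <- match(feat, FEATURE_LEVELS)
    better <- !is.na(rank) & rank < best[on_chrom]
    best[on_chrom][better] <- rank[better]
    gene_id[on_chrom][better] <- g$gene_id
  }
  mutations$feature <- FEATURE_LEVELS[best]
  mutations$gene_id <- gene_id
  mutations
}

# Spliced CDS of a gene on the coding strand, plus the genomic coordinates of
# each CDS base in coding order.
cds_sequence <- function(gene, genome) {
  seq <- genome$sequence[[gene$chrom]]
  coords <- integer(0)
  for (i in seq_len(nrow(gene$exons))) {
    cs <- max(gene$exons[i, "start"], gene$cds_start)
    ce <- min(gene$exons[i, "end"], gene$cds_end)
    if (cs <= ce) coords <- c(coords, seq.int(cs, ce))
  }
  bases <- strsplit(substr_many(seq, coords), "")[[1]]
  if (gene$strand == "-") {
    coords <- rev(coords)
    bases <- rev(rev_comp_bases(bases))
  }
  list(coords = coords, cds = paste(bases, collapse = ""))
}

substr_many <- function(seq, pos) {
  paste(substring(seq, pos, pos), collapse = "")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

rev_comp_bases <- function(bases) unname(COMPLEMENT[bases])

rev_comp <- function(x) {
  paste(rev(rev_comp_bases(strsplit(x, "")[[1]])), collapse = "")
}

# standard genetic code as a codon lookup (stops are "*")
GENETIC_CODE_MAP <- Biostrings::GENETIC_CODE

translate_codons <- function(cds) {
  starts <- seq.int(1L, nchar(cds), by = 3L)
  paste(unname(GENETIC_CODE_MAP[substring(cds, starts, starts + 2L)]),
        collapse = "")
}

#' Predict the coding effect of one mutation
#'
#' Substitutions (SBS/MNV) are evaluated by joint replacement of the affected
#' codon(s) on the coding strand: identical amino acids give `silent`, a new
#' stop gives `nonsense`, loss of the reference terminal stop gives
#' `stop_lost`, anything else `missense`. CDS indels are `frameshift` when the
#' length change is not a multiple of 3, otherwise `inframe_indel`; a
#' frameshift is flagged functionally affected when the shifted translation
#' stops before the original terminus.
#'
#' @param mutation one-row mutation data.frame (`chrom, pos, ref, alt,
#'   length, mtype`).
#' @param gene the [gene_model()] the mutation falls in (coding).
#' @param genome [genome_model()] with sequence.
#' @return list with `effect` and `functionally_affected`.
#' @export
predict_effect <- function(mutation, gene, genome) {
  if (!is_coding(gene)) return(list(effect = "noncoding",
                                    functionally_affected = FALSE))
  info <- cds_sequence(gene, genome)
  if (nchar(info$cds) %% 3 != 0) {
    warning("CDS length of ", gene$gene_id, " not divisible by 3")
    return(list(effect = NA_character_, functionally_affected = FALSE))
  }
  if (mutation$length != 0) {
    # indel: frame test plus premature-stop scan for frameshifts
    if (abs(mutation$length) %% 3 != 0) {
      affected <- frameshift_premature_stop(mutation, gene, genome, info)
      return(list(effect = "frameshift", functionally_affected = affected))
    }
    return(list(effect = "inframe_indel", functionally_affected = FALSE))
  }
  # substitution: genomic positions of the substituted bases
  gpos <- seq.int(mutation$pos, mutation$pos + nchar(mutation$ref) - 1L)
  alt_bases <- strsplit(mutation$alt, "")[[1]]
  cds_idx <- match(gpos, info$coords)
  in_cds <- !is.na(cds_idx)
  if (!any(in_cds)) return(list(effect = "noncoding",
                                functionally_affected = FALSE))
  if (gene$strand == "-") alt_bases <- rev_comp_bases(alt_bases)
  codon_idx <- sort(unique((cds_idx[in_cds] - 1L) %/% 3L + 1L))
  cds_chars <- strsplit(info$cds, "")[[1]]
  mut_chars <- cds_chars
  mut_chars[cds_idx[in_cds]] <- alt_bases[in_cds]
  ref_aa <- vapply(codon_idx, function(ci) {
    translate_codons(paste(cds_chars[(3 * ci - 2):(3 * ci)], collapse = ""))
  }, character(1))
  alt_aa <- vapply(codon_idx, function(ci) {
    translate_codons(paste(mut_chars[(3 * ci - 2):(3 * ci)], collapse = ""))
  }, character(1))
  effect <- if (all(ref_aa == alt_aa)) {
    "silent"
  } else if (any(alt_aa == "*" & ref_aa != "*")) {
    "nonsense"
  } else if (any(ref_aa == "*" & alt_aa != "*")) {
    "stop_lost"
  } else {
    "missense"
  }
  list(effect = effect,
       functionally_affected = effect %in% c("nonsense", "stop_lost"))
}

# Does a CDS frameshift indel truncate the protein before the original stop?
frameshift_premature_stop <- function(mutation, gene, genome, info) {
  seq <- genome$sequence[[gene$chrom]]
  mut_seq <- paste0(substr(seq, 1, mutation$pos - 1L), mutation$alt,
                    substr(seq, mutation$pos + nchar(mutation$ref),
                           nchar(seq)))
  shift <- nchar(mutation$alt) - nchar(mutation$ref)
  # rebuild the spliced CDS on the mutated chromosome: exon bounds after the
  # indel shift by `shift`
  edit_end <- mutation$pos + nchar(mutation$ref) - 1L
  adj <- function(p) ifelse(p > edit_end, p + shift, p)
  parts <- character(0)
  for (i in seq_len(nrow(gene$exons))) {
    cs <- max(gene$exons[i, "start"], gene$cds_start)
    ce <- min(gene$exons[i, "end"], gene$cds_end)
    if (cs <= ce) parts <- c(parts, substr(mut_seq, adj(cs), adj(ce)))
  }
  cds_mut <- paste(parts, collapse = "")
  if (gene$strand == "-") cds_mut <- rev_comp(cds_mut)
  n_codon <- nchar(cds_mut) %/% 3
  if (n_codon == 0) return(TRUE)
  aa <- translate_codons(substr(cds_mut, 1, 3 * n_codon))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  ref_codons <- nchar(info$cds) / 3
  stop_at > 0 && stop_at < ref_codons
}

#' Annotate a classified mutation table with features and coding effects
#'
#' @param mutations classified mutation data.frame.
#' @param genes list of [gene_model()] objects.
#' @param genome [genome_model()] with sequence (needed for coding effects).
#' @param config an [annotation_config()].
#' @return data.frame with `feature`, `gene_id`, `effect`,
#'   `functionally_affected` columns. `effect` is `NA` outside CDS exons.
#' @export
annotate_mutations <- function(mutations, genes, genome,
                               config = annotation_config()) {
  ann <- assign_feature(mutations, genes, config)
  ann$effect <- NA_character_
  ann$functionally_affected <- FALSE
  gene_by_id <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  for (i in seq_len(nrow(ann))) {
    if (ann$feature[i] != "exon" || is.na(ann$gene_id[i])) next
    gene <- gene_by_id[[ann$gene_id[i]]]
    if (!is_coding(gene)) {
      ann$effect[i] <- "noncoding"
      next
    }
    res <- predict_effect(ann[i, , drop = FALSE], gene, genome)
    ann$effect[i] <- res$effect
    ann$functionally_affected[i] <- res$functionally_affected
  }
  ann
}

#' Summarize coding effects and functionally affected genes
#'
#' @param annotated output of [annotate_mutations()] with a `line_id` column.
#' @param treatments optional named vector mapping line to treatment.
#' @return list with `effect_counts` (per treatment or overall: counts and
#'   percentage of missense/nonsense/stop_lost/silent among classified coding
#'   substitutions) and `affected_genes` (per line).
#' @export
effect_summary <- function(annotated, treatments = NULL) {
  grp <- if (is.null(treatments)) rep("all", nrow(annotated))
         else unname(treatments[annotated$line_id])
  coding_classes <- c("missense", "nonsense", "stop_lost", "silent")
  effect_counts <- do.call(rbind, lapply(unique(grp), function(tr) {
    eff <- annotated$effect[grp == tr & !is.na(annotated$effect) &
                              annotated$effect %in% coding_classes]
    n <- length(eff)
    cnt <- vapply(coding_classes, function(cl) sum(eff == cl), integer(1))
    data.frame(treatment = tr, effect = coding_classes, count = cnt,
               percent = if (n == 0) rep(NA_real_, length(cnt))
                         else round_half_up(100 * cnt / n, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(effect_counts) <- NULL
  aff <- annotated[annotated$functionally_affected, , drop = FALSE]
  affected_genes <- do.call(rbind, lapply(unique(annotated$line_id),
                                          function(l) {
    genes <- unique(aff$gene_id[aff$line_id == l])
    genes <- genes[!is.na(genes)]
    data.frame(line_id = l, n_affected = length(genes),
               gene_ids = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(affected_genes) <- NULL
  list(effect_counts = effect_counts, affected_genes = affected_genes)
}

#' Feature distribution per mutation class
#'
#' @param annotated output of [annotate_mutations()].
#' @param treatments optional named vector mapping line to treatment.
#' @return data.frame `treatment, mtype, feature, count, percent`; percentages
#'   sum to 100 within each (treatment, mtype).
#' @export
region_distribution <- function(annotated, treatments = NULL) {
  grp <- if (is.null(treatments)) rep("all", nrow(annotated))
         else unname(treatments[annotated$line_id])
  out <- list()
  for (tr in unique(grp)) {
    for (cl in unique(annotated$mtype[grp == tr])) {
      sel <- grp == tr & annotated$mtype == cl
      n <- sum(sel)
      cnt <- vapply(FEATURE_LEVELS, function(f) {
        sum(annotated$feature[sel] == f)
      }, integer(1))
      out[[length(out) + 1]] <- data.frame(
        treatment = tr, mtype = cl, feature = FEATURE_LEVELS, count = cnt,
        percent = round_half_up(100 * cnt / n, 2), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
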