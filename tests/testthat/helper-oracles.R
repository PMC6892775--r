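# Independent reference implementations ("oracles") used to cross-check the
# package. These deliberately use different algorithms/code paths than the
# implementation under test.

# Exact selfing-state distribution at generation g by transition-matrix power
# over states (het, hom, lost).
oracle_selfing_probs <- function(g) {
  P <- matrix(c(0.5, 0.25, 0.25,
                0.0, 1.00, 0.00,
                0.0, 0.00, 1.00),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("het", "hom", "lost"),
                              c("het", "hom", "lost")))
  v <- c(het = 1, hom = 0, lost = 0)
  if (g >= 2) for (i in seq_len(g - 1)) v <- drop(v %*% P)
  setNames(v, c("het", "hom", "lost"))
}

# Scalar brute-force re-statement of the site filter rule.
oracle_filter_site <- function(vafs, wt, focal_min = 0.25, focal_max = 1,
                               other_max = 0.10) {
  focal <- character(0)
  for (s in names(vafs)) {
    if (s == wt) next
    if (vafs[[s]] >= focal_min && vafs[[s]] <= focal_max) focal <- c(focal, s)
  }
  if (length(focal) != 1) return(NA_character_)
  for (s in names(vafs)) {
    if (s == focal) next
    if (vafs[[s]] > other_max) return(NA_character_)
  }
  focal
}

# Brute-force allele trimming: longest shared suffix then prefix, each
# leaving at least one base per allele.
oracle_trim <- function(pos, ref, alt) {
  r <- ref
  a <- alt
  while (nchar(r) > 1 && nchar(a) > 1 &&
         substring(r, nchar(r)) == substring(a, nchar(a))) {
    r <- substring(r, 1, nchar(r) - 1)
    a <- substring(a, 1, nchar(a) - 1)
  }
  while (nchar(r) > 1 && nchar(a) > 1 &&
         substring(r, 1, 1) == substring(a, 1, 1)) {
    r <- substring(r, 2)
    a <- substring(a, 2)
    pos <- pos + 1
  }
  list(pos = pos, ref = r, alt = a)
}

# Brute-force window binning by integer division per position.
oracle_window_counts <- function(pos, chrom_len, window_size) {
  n_win <- ceiling(chrom_len / window_size)
  counts <- integer(n_win)
  for (p in pos) {
    w <- ceiling(p / window_size)
    counts[w] <- counts[w] + 1L
  }
  counts
}

# Scalar per-position feature scan against one gene (independent restatement
# of the precedence rules).
oracle_gene_feature <- function(p, gene, up_bp = 5000, down_bp = 5000,
                                splice_bp = 2) {
  ex <- gene$exons
  exonic <- FALSE
  for (i in seq_len(nrow(ex))) {
    if (p >= ex[i, 1] && p <= ex[i, 2]) exonic <- TRUE
  }
  if (exonic) {
    if (!is.na(gene$cds_start) && p >= gene$cds_start && p <= gene$cds_end) {
      return("exon")
    }
    if (is.na(gene$cds_start)) return("exon")
    left_of_cds <- p < gene$cds_start
    if (gene$strand == "+") {
      return(if (left_of_cds) "UTR5" else "UTR3")
    }
    return(if (left_of_cds) "UTR3" else "UTR5")
  }
  if (p >= gene$tx_start && p <= gene$tx_end) {
    # intronic: splice region when within splice_bp of an exon edge
    for (i in seq_len(nrow(ex))) {
      if (p > ex[i, 2] && p <= ex[i, 2] + splice_bp) return("splice_region")
      if (p < ex[i, 1] && p >= ex[i, 1] - splice_bp) return("splice_region")
    }
    return("intron")
  }
  if (gene$strand == "+") {
    if (p < gene$tx_start && p >= gene$tx_start - up_bp) return("upstream")
    if (p > gene$tx_end && p <= gene$tx_end + down_bp) return("downstream")
  } else {
    if (p > gene$tx_end && p <= gene$tx_end + up_bp) return("upstream")
    if (p < gene$tx_start && p >= gene$tx_start - down_bp) return("downstream")
  }
  NA_character_
}

oracle_feature <- function(p, chrom, genes, up_bp = 5000, down_bp = 5000,
                           splice_bp = 2) {
  levels <- c("exon", "splice_region", "UTR5", "UTR3", "intron",
              "upstream", "downstream", "intergenic")
  best <- "intergenic"
  for (g in genes) {
    if (g$chrom != chrom) next
    f <- oracle_gene_feature(p, g, up_bp, down_bp, splice_bp)
    if (!is.na(f) && match(f, levels) < match(best, levels)) best <- f
  }
  best
}

# Whole-CDS retranslation oracle: apply the edit to the chromosome, rebuild
# the spliced CDS, translate the complete protein, and classify by diffing
# against the reference protein.
oracle_effect <- function(mutation, gene, genome) {
  seq <- genome$sequence[[gene$chrom]]
  splice_cds <- function(s, shift_from = NA, shift = 0) {
    parts <- character(0)
    for (i in seq_len(nrow(gene$exons))) {
      cs <- max(gene$exons[i, 1], gene$cds_start)
      ce <- min(gene$exons[i, 2], gene$cds_end)
      if (cs <= ce) {
        if (!is.na(shift_from)) {
          if (cs > shift_from) cs <- cs + shift
          if (ce > shift_from) ce <- ce + shift
        }
        parts <- c(parts, substr(s, cs, ce))
      }
    }
    paste(parts, collapse = "")
  }
  translate_str <- function(cds) {
    bases <- strsplit(cds, "")[[1]]
    if (gene$strand == "-") {
      bases <- rev(toupper(seqinr::comp(bases)))
    }
    n <- (length(bases) %/% 3) * 3
    paste(seqinr::translate(bases[seq_len(n)]), collapse = "")
  }
  ref_protein <- translate_str(splice_cds(seq))
  mut_seq <- paste0(substr(seq, 1, mutation$pos - 1), mutation$alt,
                    substr(seq, mutation$pos + nchar(mutation$ref),
                           nchar(seq)))
  shift <- nchar(mutation$alt) - nchar(mutation$ref)
  edit_end <- mutation$pos + nchar(mutation$ref) - 1
  mut_protein <- translate_str(splice_cds(mut_seq, edit_end, shift))
  if (shift != 0) {
    if (abs(shift) %% 3 != 0) {
      first_stop <- regexpr("*", mut_protein, fixed = TRUE)
      affected <- first_stop > 0 && first_stop < nchar(ref_protein)
      return(list(effect = "frameshift", functionally_affected = affected))
    }
    return(list(effect = "inframe_indel", functionally_affected = FALSE))
  }
  if (identical(ref_protein, mut_protein)) {
    return(list(effect = "silent", functionally_affected = FALSE))
  }
  ra <- strsplit(ref_protein, "")[[1]]
  ma <- strsplit(mut_protein, "")[[1]]
  if (any(ma == "*" & ra != "*")) {
    return(list(effect = "nonsense", functionally_affected = TRUE))
  }
  if (any(ra == "*" & ma != "*")) {
    return(list(effect = "stop_lost", functionally_affected = TRUE))
  }
  list(effect = "missense", functionally_affected = FALSE)
}

# Brute-force pairwise interval intersection.
oracle_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (s <= e) out[[length(out) + 1]] <- data.frame(
        chrom = a$chrom[i], start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
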