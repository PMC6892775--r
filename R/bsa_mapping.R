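#' Chi-square test of a phenotypic segregation ratio
#'
#' Pearson chi-square (no continuity correction, 1 df) of observed class
#' counts against an expected a:b ratio, the standard check that a mutant
#' phenotype segregates as a single recessive locus (3:1 in an F2).
#'
#' @param n_a,n_b observed counts of the two phenotype classes.
#' @param ratio expected ratio as `c(a, b)` (default 3:1).
#' @param alpha significance level for the consistency call.
#' @return list with `chi_square`, `p`, `consistent` (`p >= alpha`), and the
#'   expected counts.
#' @export
chi_square_segregation <- function(n_a, n_b, ratio = c(3, 1), alpha = 0.05) {
  total <- n_a + n_b
  if (total <= 0) stop("no observations")
  p_exp <- ratio / sum(ratio)
  if (any(total * p_exp == 0)) stop("zero expected count")
  ht <- suppressWarnings(
    stats::chisq.test(c(n_a, n_b), p = p_exp, correct = FALSE)
  )
  list(chi_square = unname(ht$statistic), p = ht$p.value,
       consistent = ht$p.value >= alpha,
       expected = unname(total * p_exp))
}

#' Bulk-pool marker association
#'
#' A marker is associated with the mapped (recessive) phenotype when the two
#' bulk consensus calls differ and the recessive pool is fixed for the mutant
#' parent's allele; a marker with identical parental alleles is skipped with
#' a warning.
#'
#' @param markers data.frame with columns `marker_id, chrom, position,
#'   parent1_allele, parent2_allele, pool_r_allele, pool_d_allele`, where
#'   parent 1 is the mutant.
#' @return the input rows flagged with a logical `associated` column
#'   (monomorphic markers dropped).
#' @export
pool_association <- function(markers) {
  needed <- c("marker_id", "chrom", "position", "parent1_allele",
              "parent2_allele", "pool_r_allele", "pool_d_allele")
  stopifnot(all(needed %in% names(markers)))
  mono <- markers$parent1_allele == markers$parent2_allele
  if (any(mono)) {
    warning("skipping monomorphic marker(s): ",
            paste(markers$marker_id[mono], collapse = ", "))
    markers <- markers[!mono, , drop = FALSE]
  }
  markers$associated <- markers$pool_r_allele != markers$pool_d_allele &
    markers$pool_r_allele == markers$parent1_allele
  markers
}

#' High-impact candidate mutations near an associated marker
#'
#' @param marker one-row data.frame (or list) with `chrom` and `position`.
#' @param annotated annotated mutation data.frame for the mapped line.
#' @param radius search radius in bp (default 2 Mb).
#' @param effects effect classes considered causal candidates.
#' @return the matching rows with a `distance` column, nearest first.
#' @export
candidates_near_marker <- function(marker, annotated, radius = 2e6,
                                   effects = c("nonsense", "stop_lost",
                                               "frameshift")) {
  sel <- annotated$chrom == marker$chrom &
    abs(annotated$pos - marker$position) <= radius &
    !is.na(annotated$effect) & annotated$effect %in% effects
  out <- annotated[sel, , drop = FALSE]
  out$distance <- abs(out$pos - marker$position)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward-simulate an F2 bulked-segregant experiment
#'
#' One recessive causal locus; F2 genotypes at each marker are produced by
#' sampling the two gametes with recombination between the causal locus and
#' the marker given by Haldane's map function at `morgans_per_mb` Morgans per
#' Mb. Pools are formed from phenotyped plants, and each pool's consensus call
#' per marker is the mutant allele / other allele / `"het"`.
#'
#' @param marker_positions data.frame `marker_id, chrom, position`.
#' @param causal data.frame/list with `chrom`, `position` of the causal locus.
#' @param n_plants F2 population size.
#' @param pool_size plants per phenotypic bulk.
#' @param morgans_per_mb genetic map density (default 0.04 = 4 cM/Mb).
#' @param seed optional RNG seed.
#' @return a `markers` data.frame suitable for [pool_association()], with the
#'   mutant parent as parent 1 (`allele "m"`, other parent `"p"`), plus the
#'   realized phenotype counts in attributes `n_dominant`, `n_recessive`.
#' @export
simulate_f2_pools <- function(marker_positions, causal, n_plants = 500,
                              pool_size = 20, morgans_per_mb = 0.04,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rec_frac <- function(marker) {
    if (marker$chrom != causal$chrom) return(0.5)
    d <- abs(marker$position - causal$position) / 1e6 * morgans_per_mb
    0.5 * (1 - exp(-2 * d))
  }
  # gamete: causal allele 1 = mutant; marker allele follows with prob 1 - r
  gametes <- function(r) {
    causal_allele <- stats::rbinom(n_plants, 1, 0.5)
    recomb <- stats::rbinom(n_plants, 1, r)
    marker_allele <- ifelse(recomb == 1, 1 - causal_allele, causal_allele)
    cbind(causal_allele, marker_allele)
  }
  nm <- nrow(marker_positions)
  g1_causal <- stats::rbinom(n_plants, 1, 0.5)
  g2_causal <- stats::rbinom(n_plants, 1, 0.5)
  causal_geno <- g1_causal + g2_causal  # copies of mutant allele
  phenotype <- ifelse(causal_geno == 2, "recessive", "dominant")
  r_pool <- head(which(phenotype == "recessive"), pool_size)
  d_pool <- head(which(phenotype == "dominant"), pool_size)
  # bulk consensus mimics band scoring: a pool reads as fixed when the other
  # allele falls below detection (10% of pooled DNA), mixed otherwise
  consensus <- function(copies) {
    freq <- mean(copies) / 2
    if (freq >= 0.9) "m" else if (freq <= 0.1) "p" else "het"
  }
  rows <- lapply(seq_len(nm), function(i) {
    mk <- marker_positions[i, ]
    r <- rec_frac(mk)
    recomb1 <- stats::rbinom(n_plants, 1, r)
    recomb2 <- stats::rbinom(n_plants, 1, r)
    m1 <- ifelse(recomb1 == 1, 1 - g1_causal, g1_causal)
    m2 <- ifelse(recomb2 == 1, 1 - g2_causal, g2_causal)
    copies <- m1 + m2
    data.frame(
      marker_id = mk$marker_id, chrom = mk$chrom, position = mk$position,
      parent1_allele = "m", parent2_allele = "p",
      pool_r_allele = consensus(copies[r_pool]),
      pool_d_allele = consensus(copies[d_pool]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_dominant") <- sum(phenotype == "dominant")
  attr(out, "n_recessive") <- sum(phenotype == "recessive")
  out
}
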