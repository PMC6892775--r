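#' Zygosity-state probabilities after g generations of selfing
#'
#' A new mutation arises heterozygous in the M1 plant. Each selfing
#' generation, a heterozygous mutation becomes homozygous with probability
#' 1/4, stays heterozygous with probability 1/2, and is lost with probability
#' 1/4; homozygous and lost are absorbing. At generation g this gives
#' p_het = (1/2)^(g-1) and, by symmetry, p_hom = p_lost = (1 - p_het)/2.
#'
#' @param g generation index (g = 1 is the mutagenized plant itself).
#' @return list with `generation`, `p_het`, `p_hom`, `p_lost`.
#' @export
generation_probabilities <- function(g) {
  if (g < 1) stop("generation must be >= 1")
  p_het <- 0.5^(g - 1)
  list(generation = as.integer(g), p_het = p_het,
       p_hom = (1 - p_het) / 2, p_lost = (1 - p_het) / 2)
}

#' Simulate mutation fates under selfing
#'
#' Forward-simulates the selfing transmission chain for `n_mutations`
#' independent mutations over `g` generations.
#'
#' @param n_mutations number of mutations, each starting heterozygous in M1.
#' @param g target generation (g = 1 returns all heterozygous).
#' @param seed optional RNG seed.
#' @return character vector of fates in `{"het", "hom", "lost"}`.
#' @export
simulate_selfing <- function(n_mutations, g, seed = NULL) {
  if (g < 1) stop("generation must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fate <- rep("het", n_mutations)
  for (gen in seq_len(g - 1)) {
    het <- fate == "het"
    if (!any(het)) break
    u <- runif(sum(het))
    fate[het][u < 0.25] <- "hom"
    fate[het][u >= 0.75] <- "lost"
  }
  fate
}

#' Back-estimate the number of M1 mutations
#'
#' Under the selfing model the number of lost mutations equals the number of
#' homozygous mutations at any generation, so the M1 mutation count is
#' estimated as 2 x homozygous + heterozygous (exact integer arithmetic).
#'
#' @param observed_hom,observed_het non-negative counts in the sequenced
#'   generation.
#' @return integer estimate of the M1 mutation count.
#' @export
estimate_m1 <- function(observed_hom, observed_het) {
  stopifnot(observed_hom >= 0, observed_het >= 0)
  as.integer(2L * as.integer(observed_hom) + as.integer(observed_het))
}

#' Mean M1 mutation count and per-base mutation rate for a cohort
#'
#' @param estimates integer vector of per-line M1 estimates (or a data.frame
#'   with column `estimated_m1`).
#' @param genome_length genome size in bp used as rate denominator.
#' @return list with `mean_m1` and `rate` (mutations per bp).
#' @export
cohort_mutation_rate <- function(estimates, genome_length) {
  if (is.data.frame(estimates)) estimates <- estimates$estimated_m1
  stopifnot(length(estimates) >= 1, genome_length > 0)
  mean_m1 <- mean(estimates)
  list(mean_m1 = mean_m1, rate = mean_m1 / genome_length)
}

#' Per-line M1 estimates from a classified mutation table
#'
#' @param mutations mutation data.frame with `line_id` and `zygosity`.
#' @param generations named integer vector: sequenced generation per line
#'   (recorded alongside the estimate; the estimator itself is
#'   generation-free).
#' @return data.frame `line_id, observed_hom, observed_het, estimated_m1,
#'   generation`.
#' @export
m1_estimates <- function(mutations, generations = NULL) {
  lines <- sort(unique(mutations$line_id))
  out <- do.call(rbind, lapply(lines, function(l) {
    z <- mutations$zygosity[mutations$line_id == l]
    hom <- sum(z == "homozygous")
    het <- sum(z == "heterozygous")
    data.frame(line_id = l, observed_hom = hom, observed_het = het,
               estimated_m1 = estimate_m1(hom, het),
               generation = if (is.null(generations)) NA_integer_
                            else as.integer(generations[[l]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
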