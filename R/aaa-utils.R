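DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up in magnitude, the convention
#' used for all printed percentages (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

# Welch t-test that tolerates degenerate (constant) inputs: identical groups
# give p = 1, constant but different groups give p = 0.
welch_test <- function(x, y) {
  if (stats::sd(c(x, y)) == 0 || (stats::sd(x) == 0 && stats::sd(y) == 0)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = Inf * sign(mean(x) - mean(y)), p.value = 0))
  }
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

is_dna <- function(x) {
  nchar(x) > 0 & !grepl("[^ACGT]", x)
}

stopifnot_dna <- function(ref, alt) {
  if (!all(is_dna(ref)) || !all(is_dna(alt))) {
    stop("ref/alt must be non-empty strings over {A,C,G,T}")
  }
}

empty_mutation_table <- function() {
  data.frame(
    line_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), vaf = numeric(),
    zygosity = character(), stringsAsFactors = FALSE
  )
}
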