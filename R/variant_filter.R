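#' Filter configuration for reliable-mutation calling
#'
#' Defaults encode the consensus rule used for multi-line mutant cohorts: a
#' site is a reliable line-private mutation when its variant allele frequency
#' (VAF, by read count) lies between 25% and 100% in exactly one mutant line
#' and between 0% and 10% in every other sample (wild type included), and it
#' is called homozygous when its VAF is at least 75%. All boundaries are
#' inclusive on the retaining side.
#'
#' @param focal_min_vaf minimum VAF in the focal (mutation-carrying) line.
#' @param focal_max_vaf maximum VAF in the focal line.
#' @param other_max_vaf maximum VAF tolerated in every other sample.
#' @param hom_min_vaf VAF at or above which a call is homozygous.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(focal_min_vaf = 0.25, focal_max_vaf = 1.0,
                          other_max_vaf = 0.10, hom_min_vaf = 0.75) {
  if (!(0 <= other_max_vaf && other_max_vaf < focal_min_vaf &&
        focal_min_vaf <= hom_min_vaf && hom_min_vaf <= focal_max_vaf &&
        focal_max_vaf <= 1)) {
    stop("require 0 <= other_max_vaf < focal_min_vaf <= hom_min_vaf",
         " <= focal_max_vaf <= 1")
  }
  structure(list(focal_min_vaf = focal_min_vaf, focal_max_vaf = focal_max_vaf,
                 other_max_vaf = other_max_vaf, hom_min_vaf = hom_min_vaf),
            class = "filter_config")
}

#' Variant allele frequency from read counts
#'
#' VAF = alt_depth / (ref_depth + alt_depth). A site with zero informative
#' depth is defined to have VAF 0 (with a warning): absence of read evidence
#' counts as 0% when testing the "other samples" side of the filter.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorized).
#' @return numeric VAF in \[0, 1\].
#' @export
compute_vaf <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  if (any(total == 0)) {
    warning("zero total depth: VAF defined as 0")
  }
  ifelse(total == 0, 0, alt_depth / total)
}

#' Zygosity from focal VAF
#'
#' @param vaf focal-line VAF (must already have passed the focal minimum).
#' @param config a [filter_config()].
#' @return `"homozygous"` (VAF >= `hom_min_vaf`, inclusive) or
#'   `"heterozygous"`.
#' @export
call_zygosity <- function(vaf, config = filter_config()) {
  if (any(vaf < config$focal_min_vaf)) {
    stop("zygosity is only defined for calls passing the focal VAF minimum")
  }
  ifelse(vaf >= config$hom_min_vaf, "homozygous", "heterozygous")
}

#' Apply the exclusivity filter at one site
#'
#' Given the VAF of every sample at one (chrom, pos, ref, alt) site — samples
#' with no call contribute VAF 0 — the site is retained iff exactly one
#' non-wild-type sample has VAF inside the focal window and every other
#' sample (wild type included) is at or below `other_max_vaf`.
#'
#' @param vafs named numeric vector: one VAF per cohort sample.
#' @param wild_type_id name of the wild-type sample in `vafs`.
#' @param config a [filter_config()].
#' @return `NULL` when rejected, otherwise a list with `line_id`, `vaf`,
#'   `zygosity`.
#' @export
filter_candidates <- function(vafs, wild_type_id, config = filter_config()) {
  stopifnot(!is.null(names(vafs)), wild_type_id %in% names(vafs))
  mut_samples <- setdiff(names(vafs), wild_type_id)
  focal <- mut_samples[vafs[mut_samples] >= config$focal_min_vaf &
                       vafs[mut_samples] <= config$focal_max_vaf]
  if (length(focal) != 1) return(NULL)
  others <- setdiff(names(vafs), focal)
  if (any(vafs[others] > config$other_max_vaf)) return(NULL)
  list(line_id = focal, vaf = unname(vafs[focal]),
       zygosity = call_zygosity(unname(vafs[focal]), config))
}

# VAF matrix (site x sample) for a cohort, with missing calls as 0.
vaf_matrix <- function(cohort) {
  calls <- cohort$calls
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  sites <- unique(key)
  m <- matrix(0, nrow = length(sites), ncol = length(cohort$samples),
              dimnames = list(sites, cohort$samples))
  total <- calls$ref_depth + calls$alt_depth
  vaf <- ifelse(total == 0, 0, calls$alt_depth / total)
  m[cbind(match(key, sites), match(calls$sample_id, cohort$samples))] <- vaf
  m
}

#' Filter a whole cohort to line-private mutations
#'
#' Applies [filter_candidates()] at every site of the cohort, then
#' [remove_background()]: the retained list is line-private by construction
#' and the background list collects sites shared between lines or present in
#' the wild type above the tolerance.
#'
#' @param cohort a `variant_cohort` from [read_vcf_cohort()].
#' @param config a [filter_config()].
#' @return list with `mutations` (data.frame `line_id, chrom, pos, ref, alt,
#'   vaf, zygosity`, sorted by line, chrom, pos) and `background` (data.frame
#'   `chrom, pos, ref, alt, reason`).
#' @export
filter_cohort <- function(cohort, config = filter_config()) {
  stopifnot(inherits(cohort, "variant_cohort"))
  if (nrow(cohort$calls) == 0) {
    return(list(mutations = empty_mutation_table(),
                background = data.frame(chrom = character(), pos = integer(),
                                        ref = character(), alt = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE)))
  }
  m <- vaf_matrix(cohort)
  wt <- cohort$wild_type
  mut_samples <- setdiff(cohort$samples, wt)
  focal_mask <- m[, mut_samples, drop = FALSE] >= config$focal_min_vaf &
    m[, mut_samples, drop = FALSE] <= config$focal_max_vaf
  n_focal <- rowSums(focal_mask)
  keep <- logical(nrow(m))
  line <- character(nrow(m))
  vaf <- numeric(nrow(m))
  reason <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (n_focal[i] == 1) {
      focal <- mut_samples[focal_mask[i, ]]
      others <- setdiff(cohort$samples, focal)
      if (all(m[i, others] <= config$other_max_vaf)) {
        keep[i] <- TRUE
        line[i] <- focal
        vaf[i] <- m[i, focal]
      } else if (m[i, wt] > config$other_max_vaf) {
        reason[i] <- "wild_type"
      } else {
        reason[i] <- "ambiguous"   # another line between other_max and focal_min
      }
    } else if (n_focal[i] > 1) {
      reason[i] <- "shared"
    } else if (m[i, wt] > config$other_max_vaf) {
      reason[i] <- "wild_type"
    }
  }
  parts <- strsplit(rownames(m), "\r", fixed = TRUE)
  site <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  mutations <- data.frame(
    line_id = line[keep], site[keep, , drop = FALSE],
    vaf = vaf[keep], zygosity = call_zygosity(vaf[keep], config),
    stringsAsFactors = FALSE
  )
  mutations <- mutations[order(mutations$line_id, mutations$chrom,
                               mutations$pos), , drop = FALSE]
  rownames(mutations) <- NULL
  bg_idx <- !is.na(reason)
  background <- data.frame(site[bg_idx, , drop = FALSE],
                           reason = reason[bg_idx], stringsAsFactors = FALSE)
  background <- background[order(background$chrom, background$pos), ,
                           drop = FALSE]
  rownames(background) <- NULL
  list(mutations = mutations, background = background)
}

#' Move shared and wild-type-supported sites to the background list
#'
#' Any (chrom, pos, ref, alt) attributed to more than one line, or carried by
#' the wild type above `other_max_vaf`, is a background variant (pre-existing
#' divergence from the reference), not an induced mutation.
#'
#' @param retained data.frame of mutation precursors with columns
#'   `line_id, chrom, pos, ref, alt` (and any others, carried through).
#' @param wt_vafs optional data.frame `chrom, pos, ref, alt, vaf` of wild-type
#'   support at candidate sites.
#' @param config a [filter_config()].
#' @return list with `clean` (line-private rows) and `background`.
#' @export
remove_background <- function(retained, wt_vafs = NULL,
                              config = filter_config()) {
  key <- paste(retained$chrom, retained$pos, retained$ref, retained$alt,
               sep = "\r")
  shared_keys <- names(which(tapply(retained$line_id, key,
                                    function(x) length(unique(x))) > 1))
  is_bg <- key %in% shared_keys
  if (!is.null(wt_vafs) && nrow(wt_vafs) > 0) {
    wt_key <- paste(wt_vafs$chrom, wt_vafs$pos, wt_vafs$ref, wt_vafs$alt,
                    sep = "\r")
    hot <- wt_key[wt_vafs$vaf > config$other_max_vaf]
    is_bg <- is_bg | key %in% hot
  }
  list(clean = retained[!is_bg, , drop = FALSE],
       background = retained[is_bg, , drop = FALSE])
}
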