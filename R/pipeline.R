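#' Run the core mutation-calling pipeline on a cohort VCF
#'
#' Reads the multi-sample VCF, applies the VAF exclusivity filter, normalizes
#' and classifies the retained mutations (merging consecutive substitutions
#' into MNVs) and, when gene models are supplied, annotates features and
#' coding effects.
#'
#' @param vcf path to a multi-sample VCF, or a `variant_cohort`.
#' @param genome a [genome_model()]; sequence required for left alignment,
#'   context and effect prediction.
#' @param wild_type_id wild-type sample name (used when `vcf` is a path).
#' @param genes optional list of [gene_model()] for annotation.
#' @param config a [filter_config()].
#' @param rules a [type_rules()].
#' @param annotation an [annotation_config()].
#' @return list with `mutations` (classified, possibly annotated),
#'   `background` (rejected sites with reasons) and `cohort`.
#' @export
run_pipeline <- function(vcf, genome, wild_type_id = "WT", genes = NULL,
                         config = filter_config(), rules = type_rules(),
                         annotation = annotation_config()) {
  cohort <- if (inherits(vcf, "variant_cohort")) vcf
            else read_vcf_cohort(vcf, wild_type_id)
  check_contigs(cohort$calls$chrom, genome)
  filtered <- filter_cohort(cohort, config)
  mutations <- classify_cohort(filtered$mutations, genome, rules)
  if (!is.null(genes) && nrow(mutations) > 0) {
    mutations <- annotate_mutations(mutations, genes, genome, annotation)
  }
  list(mutations = mutations, background = filtered$background,
       cohort = cohort)
}
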