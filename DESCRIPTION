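Package: radmut
Title: Mutation Profiling of Radiation-Mutagenized Re-Sequenced Plant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing mutagen-induced mutation profiles across
    whole-genome re-sequenced mutant lines. Implements consensus variant-allele
    frequency filtering of multi-sample VCF cohorts, classification of
    mutations into single-base substitutions, multi-nucleotide variants,
    small insertions/deletions and structural variants, substitution spectra
    with transition/transversion and flanking dinucleotide-context analysis,
    fixed-window mutation-density landscapes with high- and low-frequency
    region detection, gene-model based variant-effect annotation, a
    selfing-generation inheritance model with back-estimation of first
    generation mutation counts and per-base mutation rates, and bulked
    segregant analysis helpers for causal-mutation mapping. A synthetic-cohort
    generator with known ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
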