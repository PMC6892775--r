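# Small programmatic fixtures shared across tests.

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples, contigs = c(chr1 = 100000L)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(chrom, pos, ref, alt, cells) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:AD", cells),
        collapse = "\t")
}

# A deterministic miniature genome: one chromosome of repeated blocks plus a
# hand-placed coding gene, used where exact sequence content matters.
make_test_genome <- function(seq, name = "chr1") {
  genome_model(setNames(nchar(seq), name), sequence = setNames(seq, name))
}

# Small cohort config for fast tests; any cohort_config() argument can be
# overridden.
test_config <- function(...) {
  args <- list(
    n_lines = 3,
    chrom_lengths = c(chr1 = 2e5, chr2 = 1.5e5),
    per_line_mutation_count = 40,
    n_background = 20,
    genes_per_chrom = 3,
    seed = 11
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

emit_and_read <- function(truth, genome) {
  p <- tempfile(fileext = ".vcf")
  emit_cohort_vcf(truth, genome, p)
  readLines(p)
}
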