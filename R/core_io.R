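#' Construct a genome model
#'
#' A genome model holds the ordered chromosome names and lengths that act as
#' the denominator of every per-chromosome and genome-wide mutation frequency,
#' plus (optionally) the chromosome sequences used for flanking-context and
#' coding-effect analysis.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp), or a
#'   named integer vector of lengths.
#' @param sequence optional named character vector of uppercase chromosome
#'   sequences; names and lengths must match `chromosomes`.
#' @return an object of class `genome_model` with elements `chromosomes`
#'   (data.frame) and `sequence` (named character vector or NULL).
#' @export
genome_model <- function(chromosomes, sequence = NULL) {
  if (!is.data.frame(chromosomes)) {
    chromosomes <- data.frame(
      name = names(chromosomes),
      length = as.integer(unname(chromosomes)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  chromosomes$length <- as.integer(chromosomes$length)
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (!setequal(names(sequence), chromosomes$name)) {
      stop("sequence names do not match declared chromosomes")
    }
    sequence <- sequence[chromosomes$name]
    if (!all(nchar(sequence) == chromosomes$length)) {
      stop("sequence lengths do not match declared chromosome lengths")
    }
  }
  structure(list(chromosomes = chromosomes, sequence = sequence),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      sum(as.numeric(x$chromosomes$length)), "bp",
      if (is.null(x$sequence)) "(lengths only)" else "(with sequence)", "\n")
  invisible(x)
}

genome_length <- function(genome) sum(as.numeric(genome$chromosomes$length))

#' Construct a gene model
#'
#' One transcript-level gene model: stranded exon structure plus an optional
#' CDS interval, all coordinates 1-based inclusive on the reference.
#'
#' @param gene_id identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end transcript bounds.
#' @param exons two-column matrix or data.frame of exon (start, end) pairs.
#' @param cds_start,cds_end CDS bounds, or `NA` for a non-coding model.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end, exons,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "start"] > exons[, "end"])) stop("malformed exon interval")
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] <= exons[-nrow(exons), "end"])) {
    stop("exons overlap")
  }
  if (exons[1, "start"] < tx_start || exons[nrow(exons), "end"] > tx_end) {
    stop("exons outside transcript bounds")
  }
  if (!is.na(cds_start)) {
    if (cds_start > cds_end) stop("malformed CDS interval")
    in_exon <- function(p) any(p >= exons[, "start"] & p <= exons[, "end"])
    if (!in_exon(cds_start) || !in_exon(cds_end)) {
      stop("CDS bounds fall outside exons for gene ", gene_id)
    }
  }
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  ), class = "gene_model")
}

is_coding <- function(gene) !is.na(gene$cds_start)

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return a [genome_model()] with sequence (uppercased).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  sequence <- toupper(as.character(seqs))
  names(sequence) <- nm
  genome_model(
    data.frame(name = nm, length = nchar(sequence), stringsAsFactors = FALSE),
    sequence = sequence
  )
}

#' Write a genome model to FASTA
#'
#' @param genome a [genome_model()] with sequence.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop("genome model has no sequence")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequence), path
  )
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds one [gene_model()] per mRNA feature; exon and CDS children are
#' attached by their `Parent` attribute. Transcripts without CDS children are
#' non-coding models.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return list of `gene_model` objects.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path)
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  if (length(mrna) == 0) stop("no mRNA features in ", path)
  parent_of <- function(feat) {
    vapply(feat$Parent, function(p) as.character(p)[1], character(1))
  }
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  exon_parent <- parent_of(exons)
  cds_parent <- if (length(cds)) parent_of(cds) else character(0)
  lapply(seq_along(mrna), function(i) {
    tx <- mrna[i]
    tx_id <- as.character(tx$ID)
    ex <- exons[exon_parent == tx_id]
    if (length(ex) == 0) {
      ex_mat <- cbind(start = GenomicRanges::start(tx),
                      end = GenomicRanges::end(tx))
    } else {
      ex_mat <- cbind(start = GenomicRanges::start(ex),
                      end = GenomicRanges::end(ex))
    }
    cd <- cds[cds_parent == tx_id]
    cds_start <- if (length(cd)) min(GenomicRanges::start(cd)) else NA_integer_
    cds_end <- if (length(cd)) max(GenomicRanges::end(cd)) else NA_integer_
    gene_model(
      gene_id = tx_id,
      chrom = as.character(GenomicRanges::seqnames(tx)),
      strand = as.character(GenomicRanges::strand(tx)),
      tx_start = GenomicRanges::start(tx), tx_end = GenomicRanges::end(tx),
      exons = ex_mat, cds_start = cds_start, cds_end = cds_end
    )
  })
}

#' Write gene models to GFF3
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gff <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    gid <- g$gene_id
    lines <- c(lines,
      paste(g$chrom, "radmut", "gene", g$tx_start, g$tx_end, ".", g$strand,
            ".", sprintf("ID=gene:%s", gid), sep = "\t"),
      paste(g$chrom, "radmut", "mRNA", g$tx_start, g$tx_end, ".", g$strand,
            ".", sprintf("ID=%s;Parent=gene:%s", gid, gid), sep = "\t"))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines,
        paste(g$chrom, "radmut", "exon", g$exons[i, "start"],
              g$exons[i, "end"], ".", g$strand, ".",
              sprintf("ID=%s.exon%d;Parent=%s", gid, i, gid), sep = "\t"))
    }
    if (is_coding(g)) {
      for (i in seq_len(nrow(g$exons))) {
        cs <- max(g$exons[i, "start"], g$cds_start)
        ce <- min(g$exons[i, "end"], g$cds_end)
        if (cs <= ce) {
          lines <- c(lines,
            paste(g$chrom, "radmut", "CDS", cs, ce, ".", g$strand, "0",
                  sprintf("ID=%s.cds%d;Parent=%s", gid, i, gid), sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-sample VCF cohort
#'
#' Expands a VCF 4.2 file into one per-sample, per-alt-allele variant call
#' with AD-based read support. Multi-allelic records are split into biallelic
#' calls before any filtering. A sample contributes a call at a site only when
#' it has alt-supporting reads or a non-reference genotype; absence of a call
#' is later interpreted as 0% variant allele frequency.
#'
#' @param path VCF file (FORMAT must include AD as ref,alt depths).
#' @param wild_type_id sample name of the non-mutagenized wild type.
#' @return object of class `variant_cohort`: list with `calls` (data.frame
#'   `sample_id, chrom, pos, ref, alt, ref_depth, alt_depth`), `samples`
#'   (all sample names in header order) and `wild_type`.
#' @export
read_vcf_cohort <- function(path, wild_type_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!wild_type_id %in% samples) {
    stop("wild-type sample '", wild_type_id, "' absent from VCF header")
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- vcf@gt[, "FORMAT"]
  no_ad <- !grepl("(^|:)AD(:|$)", fmt)
  if (any(no_ad)) {
    i <- which(no_ad)[1]
    stop("missing AD FORMAT field at record ", fix[i, "CHROM"], ":",
         fix[i, "POS"])
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ad_i <- strsplit(ad[i, ], ",", fixed = TRUE)
    rows <- list()
    for (s in samples) {
      depths <- suppressWarnings(as.integer(ad_i[[s]]))
      if (length(depths) < 1 || all(is.na(depths))) next
      ref_d <- depths[1]
      gt_s <- gt[i, s]
      for (k in seq_along(alts)) {
        alt_d <- if (length(depths) >= k + 1) depths[k + 1] else 0L
        if (is.na(alt_d)) alt_d <- 0L
        nonref_gt <- !is.na(gt_s) &&
          grepl(as.character(k), gsub("[|/]", " ", gt_s), fixed = TRUE)
        if (alt_d >= 1L || nonref_gt) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = s, chrom = fix[i, "CHROM"],
            pos = as.integer(fix[i, "POS"]),
            ref = toupper(fix[i, "REF"]), alt = toupper(alts[k]),
            ref_depth = ifelse(is.na(ref_d), 0L, ref_d), alt_depth = alt_d,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        ref_depth = integer(), alt_depth = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  structure(list(calls = calls, samples = samples, wild_type = wild_type_id),
            class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("variant_cohort:", nrow(x$calls), "calls across",
      length(x$samples), "samples (wild type:", x$wild_type, ")\n")
  invisible(x)
}

# Hard error when calls mention contigs the genome model does not declare —
# silently dropping them would corrupt every per-chromosome frequency.
check_contigs <- function(chroms, genome) {
  unknown <- setdiff(unique(chroms), genome$chromosomes$name)
  if (length(unknown)) {
    stop("contig(s) absent from genome model: ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write result tables as TSV (and BED where the table is interval-shaped)
#'
#' Every data.frame in `results` is written as `<name>.tsv` with its in-memory
#' column order. Tables carrying `chrom`, `start`, `end` columns (windows,
#' HF/LF regions) are additionally written as `<name>.bed` in 0-based
#' half-open BED convention; all in-memory coordinates are 1-based inclusive.
#'
#' @param results named list of data.frames (a bare data.frame is accepted).
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of files written.
#' @export
write_tables <- function(results, out_dir) {
  if (is.data.frame(results)) results <- list(result = results)
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) next
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
    if (all(c("chrom", "start", "end") %in% names(df))) {
      bed <- file.path(out_dir, paste0(nm, ".bed"))
      bed_df <- data.frame(df$chrom, as.integer(df$start) - 1L,
                           as.integer(df$end))
      utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      written <- c(written, bed)
    }
  }
  invisible(written)
}

#' Read back a TSV written by [write_tables()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
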