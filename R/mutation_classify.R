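#' Size rules for mutation typing
#'
#' Insertions/deletions of 1–10 bp are InDels and of more than 50 bp are
#' structural variants (SVs); substitutions at two or more strictly
#' consecutive bases are multi-nucleotide variants (MNVs). Length changes of
#' 11–50 bp fall outside these definitions and are reported in an explicit
#' `unclassified` bucket rather than silently lumped.
#'
#' @param indel_min,indel_max InDel size bounds (bp).
#' @param sv_min minimum SV size (bp; ">50 bp" means 51).
#' @param mnv_min_run minimum run of consecutive substituted bases for an MNV.
#' @return object of class `type_rules`.
#' @export
type_rules <- function(indel_min = 1L, indel_max = 10L, sv_min = 51L,
                       mnv_min_run = 2L) {
  stopifnot(indel_max < sv_min, indel_min >= 1, mnv_min_run >= 2)
  structure(list(indel_min = indel_min, indel_max = indel_max,
                 sv_min = sv_min, mnv_min_run = mnv_min_run),
            class = "type_rules")
}

# Trim one ref/alt pair to normal form: shared trailing then leading bases
# removed, keeping a leading anchor base for pure indels (VCF convention).
trim_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # trailing
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # leading
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# Left-align one variant against the reference: repeatedly drop a shared
# trailing base and, whenever an allele empties, re-anchor one base to the
# left. Terminates at the leftmost equivalent representation.
left_align <- function(pos, ref, alt, seq) {
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    changed <- FALSE
    if (nchar(ref) > 0 && nchar(alt) > 0 && last(ref) == last(alt) &&
        (nchar(ref) > 1 || nchar(alt) > 1) &&
        !(pos == 1 && (nchar(ref) == 1 || nchar(alt) == 1))) {
      ref <- substr(ref, 1, nchar(ref) - 1L)
      alt <- substr(alt, 1, nchar(alt) - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      b <- substr(seq, pos - 1L, pos - 1L)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # re-trim shared leading bases accumulated while shifting
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize a variant to canonical trimmed, left-aligned form
#'
#' Shared leading/trailing bases are trimmed (a leading anchor base is kept
#' for pure indels, per VCF convention), and indels are left-aligned against
#' the reference sequence when one is supplied. The signed length change is
#' `nchar(alt) - nchar(ref)`.
#'
#' @param mutations data.frame with `chrom, pos, ref, alt` (other columns
#'   carried through).
#' @param genome optional [genome_model()] with sequence, for left alignment.
#' @return the data.frame with normalized `pos, ref, alt` and a `length`
#'   column (insertions positive, deletions negative, substitutions 0).
#' @export
normalize_variants <- function(mutations, genome = NULL) {
  stopifnot_dna(mutations$ref, mutations$alt)
  if (any(mutations$ref == mutations$alt)) {
    stop("ref equals alt: not a variant")
  }
  n <- nrow(mutations)
  for (i in seq_len(n)) {
    tr <- trim_alleles(mutations$pos[i], mutations$ref[i], mutations$alt[i])
    if (tr$ref == tr$alt) stop("ref equals alt after trimming at row ", i)
    if (!is.null(genome) && !is.null(genome$sequence) &&
        nchar(tr$ref) != nchar(tr$alt)) {
      seq <- genome$sequence[[mutations$chrom[i]]]
      tr <- left_align(tr$pos, tr$ref, tr$alt, seq)
    }
    mutations$pos[i] <- tr$pos
    mutations$ref[i] <- tr$ref
    mutations$alt[i] <- tr$alt
  }
  mutations$length <- nchar(mutations$alt) - nchar(mutations$ref)
  mutations
}

#' Merge runs of consecutive single-base substitutions into MNVs
#'
#' Within each line, maximal runs of single-base substitutions at strictly
#' consecutive positions (pos, pos+1, ...) on one chromosome are merged into
#' one multi-base substitution record. The merged record is homozygous only
#' when every member is homozygous; its VAF is the member mean.
#'
#' @param mutations normalized mutation data.frame (`line_id, chrom, pos, ref,
#'   alt, length`, optionally `vaf, zygosity`).
#' @return data.frame with runs merged; non-substitution records untouched.
#' @export
merge_mnv <- function(mutations) {
  if (nrow(mutations) == 0) return(mutations)
  is_sbs <- mutations$length == 0 & nchar(mutations$ref) == 1
  sub <- mutations[is_sbs, , drop = FALSE]
  rest <- mutations[!is_sbs, , drop = FALSE]
  if (nrow(sub) == 0) return(mutations)
  key <- paste(sub$line_id, sub$chrom, sub$pos)
  if (anyDuplicated(key)) {
    stop("duplicate substitution position within one line")
  }
  sub <- sub[order(sub$line_id, sub$chrom, sub$pos), , drop = FALSE]
  new_run <- c(TRUE, !(sub$line_id[-1] == sub$line_id[-nrow(sub)] &
                       sub$chrom[-1] == sub$chrom[-nrow(sub)] &
                       sub$pos[-1] == sub$pos[-nrow(sub)] + 1L))
  run_id <- cumsum(new_run)
  merged <- do.call(rbind, lapply(split(sub, run_id), function(r) {
    out <- r[1, , drop = FALSE]
    if (nrow(r) > 1) {
      out$ref <- paste(r$ref, collapse = "")
      out$alt <- paste(r$alt, collapse = "")
      if ("vaf" %in% names(r)) out$vaf <- mean(r$vaf)
      if ("zygosity" %in% names(r)) {
        out$zygosity <- if (all(r$zygosity == "homozygous")) "homozygous"
                        else "heterozygous"
      }
    }
    out
  }))
  out <- rbind(merged, rest)
  out <- out[order(out$line_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each mutation one of SBS / MNV / InDel / SV / unclassified
#'
#' @param mutations normalized, MNV-merged mutation data.frame.
#' @param rules a [type_rules()].
#' @return the data.frame with an `mtype` column.
#' @export
classify_mutations <- function(mutations, rules = type_rules()) {
  len <- mutations$length
  span <- nchar(mutations$ref)
  mtype <- rep("unclassified", nrow(mutations))
  mtype[len == 0 & span == 1] <- "SBS"
  mtype[len == 0 & span >= rules$mnv_min_run] <- "MNV"
  mtype[abs(len) >= rules$indel_min & abs(len) <= rules$indel_max] <- "InDel"
  mtype[abs(len) >= rules$sv_min] <- "SV"
  mutations$mtype <- mtype
  mutations
}

#' Normalize, merge and classify in one step
#'
#' @param mutations filtered mutation data.frame from [filter_cohort()].
#' @param genome optional [genome_model()] for indel left alignment.
#' @param rules a [type_rules()].
#' @return classified mutation data.frame.
#' @export
classify_cohort <- function(mutations, genome = NULL, rules = type_rules()) {
  if (nrow(mutations) == 0) {
    mutations$length <- integer(0)
    mutations$mtype <- character(0)
    return(mutations)
  }
  m <- normalize_variants(mutations, genome)
  m <- merge_mnv(m)
  classify_mutations(m, rules)
}
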