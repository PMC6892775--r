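SUB_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                 "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Directional 12-class substitution spectrum
#'
#' Counts each single-base substitution on the reference strand without
#' collapsing reverse complements, so G>A and C>T are reported separately.
#'
#' @param mutations data.frame of SBS records (`ref`, `alt` single bases).
#' @return named integer vector over the 12 directional classes.
#' @export
substitution_spectrum <- function(mutations) {
  if (nrow(mutations) == 0) {
    return(setNames(integer(length(SUB_CLASSES)), SUB_CLASSES))
  }
  if (any(nchar(mutations$ref) != 1 | nchar(mutations$alt) != 1)) {
    stop("substitution_spectrum expects single-base substitutions only")
  }
  cls <- paste0(mutations$ref, ">", mutations$alt)
  if (!all(cls %in% SUB_CLASSES)) stop("invalid substitution class")
  counts <- table(factor(cls, levels = SUB_CLASSES))
  setNames(as.integer(counts), SUB_CLASSES)
}

#' Transition/transversion ratio from a 12-class spectrum
#'
#' Transitions are A>G, G>A, C>T, T>C; everything else is a transversion.
#'
#' @param counts named vector over the 12 directional classes.
#' @return list with `n_transitions`, `n_transversions`, `titv` (`NA` when
#'   there are no transversions, in which case the ratio is undefined).
#' @export
titv_ratio <- function(counts) {
  stopifnot(all(SUB_CLASSES %in% names(counts)))
  ti <- sum(counts[TRANSITIONS])
  tv <- sum(counts[setdiff(SUB_CLASSES, TRANSITIONS)])
  list(n_transitions = ti, n_transversions = tv,
       titv = if (tv == 0) NA_real_ else ti / tv)
}

#' Flanking dinucleotide context of G>A or C>T transitions
#'
#' A G>A site is "in context" when the reference base immediately 5' or
#' immediately 3' of the mutated base is a purine (A/G), forming a purine
#' dinucleotide; C>T sites are tested against pyrimidine (C/T) neighbors.
#' Chromosome-end sites are judged on their single existing neighbor. The
#' analysis is strictly on the reference strand.
#'
#' @param mutations SBS data.frame (`chrom, pos, ref, alt`).
#' @param genome [genome_model()] with sequence.
#' @param target_class `"G>A"` or `"C>T"`.
#' @param side which neighbor may establish context: `"either"` (default),
#'   `"5prime"` or `"3prime"`.
#' @return list with `n_in_context`, `n_total`, `percent`, and a `sites`
#'   data.frame naming each site and its flanking bases.
#' @export
dinucleotide_context <- function(mutations, genome,
                                 target_class = c("G>A", "C>T"),
                                 side = c("either", "5prime", "3prime")) {
  target_class <- match.arg(target_class)
  side <- match.arg(side)
  if (is.null(genome$sequence)) stop("genome sequence required")
  ref_base <- substr(target_class, 1, 1)
  alt_base <- substr(target_class, 3, 3)
  partners <- if (ref_base == "G") PURINES else PYRIMIDINES
  sel <- mutations[mutations$ref == ref_base & mutations$alt == alt_base, ,
                   drop = FALSE]
  n_total <- nrow(sel)
  if (n_total == 0) {
    return(list(n_in_context = 0L, n_total = 0L, percent = NA_real_,
                sites = data.frame()))
  }
  check_contigs(sel$chrom, genome)
  five <- character(n_total)
  three <- character(n_total)
  for (i in seq_len(n_total)) {
    seq <- genome$sequence[[sel$chrom[i]]]
    p <- sel$pos[i]
    if (substr(seq, p, p) != ref_base) {
      stop("reference base mismatch at ", sel$chrom[i], ":", p)
    }
    five[i] <- if (p > 1) substr(seq, p - 1, p - 1) else ""
    three[i] <- if (p < nchar(seq)) substr(seq, p + 1, p + 1) else ""
  }
  in5 <- five %in% partners
  in3 <- three %in% partners
  in_context <- switch(side, either = in5 | in3, `5prime` = in5,
                       `3prime` = in3)
  sites <- data.frame(chrom = sel$chrom, pos = sel$pos,
                      five_prime = five, three_prime = three,
                      in_context = in_context, stringsAsFactors = FALSE)
  list(n_in_context = sum(in_context), n_total = n_total,
       percent = round_half_up(100 * sum(in_context) / n_total, 2),
       sites = sites)
}

#' InDel size spectrum
#'
#' @param mutations InDel records with signed `length` (deletions negative).
#' @return list with `histogram` (named counts over -10..-1, +1..+10),
#'   `deletion_fraction` and `multi_base_deletion_count` (deletions of 5 bp or
#'   more).
#' @export
indel_size_spectrum <- function(mutations) {
  len <- mutations$length
  if (any(len == 0)) stop("indel_size_spectrum expects non-zero lengths")
  lv <- c(-10:-1, 1:10)
  histogram <- setNames(as.integer(table(factor(len, levels = lv))),
                        as.character(lv))
  n <- length(len)
  list(
    histogram = histogram,
    deletion_fraction = if (n == 0) NA_real_ else sum(len < 0) / n,
    multi_base_deletion_count = sum(len <= -5L)
  )
}

#' Per-line and per-treatment mutation summary
#'
#' Per-line counts and percentage shares of SBS / MNV / InDel / SV, treatment
#' means, cross-treatment mean ratios, and Welch t-tests on per-line counts
#' between the two treatments (when exactly two are present).
#'
#' @param mutations classified mutation data.frame (`line_id`, `mtype`).
#' @param treatments named character vector mapping line_id to treatment.
#' @return list with `per_line` (data.frame), `per_treatment` (means),
#'   `mean_ratios` (second/first treatment per class) and `t_tests`.
#' @export
treatment_summary <- function(mutations, treatments) {
  lines <- names(treatments)
  unknown <- setdiff(unique(mutations$line_id), lines)
  if (length(unknown)) {
    stop("line(s) mapped to no treatment: ", paste(unknown, collapse = ", "))
  }
  classes <- c("SBS", "MNV", "InDel", "SV")
  counts <- sapply(classes, function(cl) {
    vapply(lines, function(l) {
      sum(mutations$line_id == l & mutations$mtype == cl)
    }, integer(1))
  })
  counts <- matrix(counts, nrow = length(lines),
                   dimnames = list(lines, classes))
  total <- rowSums(counts)
  prop <- 100 * counts / ifelse(total == 0, NA, total)
  per_line <- data.frame(
    line_id = lines, treatment = unname(treatments[lines]),
    total = total, counts, round_half_up(prop, 2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(per_line) <- c("line_id", "treatment", "total", classes,
                       paste0("pct_", classes))
  rownames(per_line) <- NULL
  tr_levels <- unique(unname(treatments[lines]))
  per_treatment <- do.call(rbind, lapply(tr_levels, function(tr) {
    sel <- per_line$treatment == tr
    data.frame(treatment = tr, n_lines = sum(sel),
               total = round_half_up(mean(per_line$total[sel]), 2),
               t(round_half_up(colMeans(counts[sel, , drop = FALSE]), 2)),
               stringsAsFactors = FALSE)
  }))
  mean_ratios <- NULL
  t_tests <- NULL
  if (length(tr_levels) == 2) {
    m1 <- per_treatment[per_treatment$treatment == tr_levels[1], classes]
    m2 <- per_treatment[per_treatment$treatment == tr_levels[2], classes]
    mean_ratios <- setNames(as.numeric(m2) / as.numeric(m1), classes)
    t_tests <- lapply(setNames(classes, classes), function(cl) {
      x <- counts[per_line$treatment == tr_levels[1], cl]
      y <- counts[per_line$treatment == tr_levels[2], cl]
      welch_test(x, y)
    })
  }
  list(per_line = per_line, per_treatment = per_treatment,
       mean_ratios = mean_ratios, t_tests = t_tests)
}
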