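#' Per-chromosome mutation frequency
#'
#' @param mutations mutation data.frame with `chrom` (and `pos`).
#' @param genome [genome_model()].
#' @return data.frame `chrom, length, count, kb_per_mutation, per_bp_rate`;
#'   chromosomes with zero mutations report `NA` spacing and rate 0.
#' @export
chromosome_frequency <- function(mutations, genome) {
  check_contigs(mutations$chrom, genome)
  chroms <- genome$chromosomes
  count <- vapply(chroms$name, function(ch) sum(mutations$chrom == ch),
                  integer(1))
  data.frame(
    chrom = chroms$name,
    length = chroms$length,
    count = count,
    kb_per_mutation = ifelse(count == 0, NA_real_,
                             (chroms$length / 1000) / count),
    per_bp_rate = count / chroms$length,
    stringsAsFactors = FALSE
  )
}

#' Count mutations in non-overlapping fixed windows
#'
#' Windows tile each chromosome from position 1 (1-based inclusive bounds);
#' the last window may be short. A mutation at the exact window end belongs to
#' that window.
#'
#' @param mutations mutation data.frame (`chrom, pos`).
#' @param genome [genome_model()].
#' @param window_size window width in bp (1 Mb default; 100 kb for the
#'   fine-grained landscape).
#' @param treatment optional label stored on every row.
#' @return data.frame `chrom, start, end, count, frequency, treatment`
#'   (frequency = count per bp of window).
#' @export
window_counts <- function(mutations, genome, window_size = 1e6,
                          treatment = NA_character_) {
  stopifnot(window_size > 0)
  check_contigs(mutations$chrom, genome)
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    ch <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    starts <- seq.int(1L, len, by = window_size)
    ends <- pmin(starts + window_size - 1, len)
    pos <- mutations$pos[mutations$chrom == ch]
    idx <- floor((pos - 1) / window_size) + 1
    count <- tabulate(idx, nbins = length(starts))
    data.frame(chrom = ch, start = starts, end = ends, count = count,
               frequency = count / (ends - starts + 1),
               treatment = treatment, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect high- and low-frequency mutation regions
#'
#' A window is high-frequency (HF) when its mutation frequency is at least
#' `hf_multiplier` times the mean frequency of its chromosome and it holds at
#' least `min_count` mutations; a window is low-frequency (LF) when it holds
#' none. Adjacent qualifying windows are merged into regions.
#'
#' @param windows output of [window_counts()] for one treatment.
#' @param hf_multiplier fold-change over the chromosome mean (default 4).
#' @param min_count minimum mutations in an HF window (default 2).
#' @return data.frame `chrom, start, end, count, frequency,
#'   chromosome_mean_frequency, label` with label HF or LF.
#' @export
detect_hf_lf <- function(windows, hf_multiplier = 4.0, min_count = 2L) {
  out <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$start), , drop = FALSE]
    chrom_len <- sum(w$end - w$start + 1)
    mean_freq <- sum(w$count) / chrom_len
    label <- rep(NA_character_, nrow(w))
    label[w$count == 0] <- "LF"
    label[w$frequency >= hf_multiplier * mean_freq & w$count >= min_count &
            mean_freq > 0] <- "HF"
    keep <- which(!is.na(label))
    if (length(keep) == 0) return(NULL)
    # merge runs of adjacent windows sharing a label
    grp <- cumsum(c(TRUE, diff(keep) != 1 |
                      label[keep][-1] != label[keep][-length(keep)]))
    do.call(rbind, lapply(split(keep, grp), function(ix) {
      data.frame(
        chrom = w$chrom[1], start = w$start[ix[1]],
        end = w$end[ix[length(ix)]], count = sum(w$count[ix]),
        frequency = sum(w$count[ix]) /
          (w$end[ix[length(ix)]] - w$start[ix[1]] + 1),
        chromosome_mean_frequency = mean_freq,
        label = label[ix[1]], stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), count = integer(),
                      frequency = numeric(),
                      chromosome_mean_frequency = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Welch t-test of HF versus LF region frequencies
#'
#' @param hf,lf data.frames of regions (column `frequency`), at least two
#'   regions each.
#' @return list with `statistic` and `p.value` (two-sided).
#' @export
compare_hf_lf <- function(hf, lf) {
  if (nrow(hf) < 2 || nrow(lf) < 2) {
    stop("need at least two regions per group")
  }
  welch_test(hf$frequency, lf$frequency)
}

#' Common HF regions across treatments
#'
#' Intersects region sets pairwise across all treatments; a common region is
#' an interval flagged in every treatment.
#'
#' @param regions_by_treatment named list of region data.frames
#'   (`chrom, start, end`).
#' @return data.frame `chrom, start, end` of intersections (1-based
#'   inclusive), empty when disjoint.
#' @export
common_hf_regions <- function(regions_by_treatment) {
  stopifnot(length(regions_by_treatment) >= 2)
  as_gr <- function(df) {
    if (nrow(df) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start, df$end))
  }
  acc <- as_gr(regions_by_treatment[[1]])
  for (df in regions_by_treatment[-1]) {
    acc <- suppressWarnings(GenomicRanges::intersect(acc, as_gr(df)))
  }
  if (length(acc) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(acc)),
             start = GenomicRanges::start(acc),
             end = GenomicRanges::end(acc), stringsAsFactors = FALSE)
}

#' Fraction of InDels accompanied by a nearby SBS
#'
#' For each InDel (pooled across one treatment's lines) tests whether any SBS
#' lies within `distance` bp on the same chromosome.
#'
#' @param mutations classified mutation data.frame (`mtype, chrom, pos`).
#' @param distance proximity radius in bp (default 10 kb).
#' @return list with `fraction`, `n_accompanied`, `n_indels`.
#' @export
indel_sbs_proximity <- function(mutations, distance = 1e4) {
  indels <- mutations[mutations$mtype == "InDel", , drop = FALSE]
  sbs <- mutations[mutations$mtype == "SBS", , drop = FALSE]
  if (nrow(indels) == 0) {
    return(list(fraction = NA_real_, n_accompanied = 0L, n_indels = 0L))
  }
  acc <- vapply(seq_len(nrow(indels)), function(i) {
    p <- sbs$pos[sbs$chrom == indels$chrom[i]]
    any(abs(p - indels$pos[i]) <= distance)
  }, logical(1))
  list(fraction = sum(acc) / nrow(indels),
       n_accompanied = sum(acc), n_indels = nrow(indels))
}

#' InDel–SBS proximity at several radii
#'
#' @param mutations classified mutation data.frame.
#' @param distances radii in bp.
#' @return data.frame `distance, fraction, n_accompanied, n_indels`.
#' @export
proximity_sensitivity <- function(mutations,
                                  distances = c(1e3, 5e3, 1e4, 5e4)) {
  do.call(rbind, lapply(distances, function(d) {
    r <- indel_sbs_proximity(mutations, d)
    data.frame(distance = d, fraction = r$fraction,
               n_accompanied = r$n_accompanied, n_indels = r$n_indels)
  }))
}
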