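#' Strand-aware peak calling on a normalized coverage track
#'
#' A deliberately minimal caller: the genome-wide background rate `lambda`
#' is a trimmed mean of all bin values (top `trim` fraction excluded, so
#' enriched regions do not inflate it). Bins with value at least
#' `min_fold * lambda` and an upper-tail Poisson probability below
#' `p_cutoff` are candidates; candidate runs separated by at most
#' `merge_gap` bases are merged; merged peaks shorter than `min_size`
#' (default 200 bp) are discarded. The summit is the midpoint of the
#' highest bin; the score is the mean bin value over the peak; strand is
#' inherited from the track.
#'
#' @param track a normalized `SignalTrack` (one strand or `both`).
#' @param genome a `GenomeRef` (chromosome bounds).
#' @param min_fold minimum fold over background (> 1, default 5).
#' @param merge_gap merge candidate runs separated by at most this many
#'   bases (default: one bin).
#' @param min_size discard peaks shorter than this (default 200 bp).
#' @param p_cutoff Poisson upper-tail cutoff (default 0.01).
#' @param trim fraction of top bins excluded from the background mean.
#' @return a `RegionSet` of peaks with extra columns `summit` and
#'   `pvalue`; empty for a flat-zero track.
#' @export
call_peaks <- function(track, genome, min_fold = 5,
                       merge_gap = track$bin_size, min_size = 200,
                       p_cutoff = 0.01, trim = 0.01) {
  stopifnot(inherits(track, "SignalTrack"), min_fold > 1)
  v_all <- unlist(track$values, use.names = FALSE)
  if (!length(v_all) || all(v_all == 0)) {
    return(empty_peaks())
  }
  cutoff <- stats::quantile(v_all, 1 - trim, names = FALSE)
  lambda <- mean(v_all[v_all <= cutoff])
  if (lambda == 0) {
    # almost-everywhere-zero track: fall back to the overall mean
    lambda <- mean(v_all)
  }
  bs <- track$bin_size
  out <- list()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    cand <- v >= min_fold * lambda &
      stats::ppois(ceiling(v) - 1, lambda, lower.tail = FALSE) < p_cutoff &
      v > 0
    if (!any(cand)) next
    idx <- which(cand)
    gap_bins <- max(0L, floor(merge_gap / bs))
    grp <- cumsum(c(1L, diff(idx) > gap_bins + 1L))
    for (g in unique(grp)) {
      bins <- idx[grp == g]
      start <- (bins[1L] - 1L) * bs
      end <- min(bins[length(bins)] * bs, genome$chrom_lengths[[ch]])
      if (end - start < min_size) next
      vmax <- bins[which.max(v[bins])]
      summit <- min((vmax - 1L) * bs + bs %/% 2, end - 1L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end,
        score = mean(v[bins]),
        summit = summit,
        pvalue = stats::ppois(ceiling(max(v[bins])) - 1, lambda,
                              lower.tail = FALSE)
      )
    }
  }
  if (!length(out)) return(empty_peaks())
  df <- do.call(rbind, out)
  peaks <- region_set(df$chrom, df$start, df$end,
                      name = sprintf("peak_%d", seq_len(nrow(df))),
                      score = df$score,
                      strand = if (track$strand == "both") "." else track$strand)
  peaks$summit <- df$summit
  peaks$pvalue <- df$pvalue
  sort_regions(peaks)
}

empty_peaks <- function() {
  p <- region_set()
  p$summit <- numeric(0)
  p$pvalue <- numeric(0)
  p
}

#' Peak recall/precision against a truth region set
#'
#' A truth region is recovered if some peak overlaps it; a peak is a true
#' positive if it overlaps some truth region. Strand must match when both
#' sides carry one.
#'
#' @param peaks,truth `RegionSet`s.
#' @return list with `recall`, `precision`, and the overlap counts.
#' @export
peak_truth_stats <- function(peaks, truth) {
  if (nrow(peaks) == 0L) {
    return(list(recall = 0, precision = NA_real_, n_peaks = 0L,
                n_truth = nrow(truth)))
  }
  pg <- regions_to_granges(peaks)
  tg <- regions_to_granges(truth)
  stranded <- any(peaks$strand != ".") && any(truth$strand != ".")
  ov <- GenomicRanges::findOverlaps(pg, tg, ignore.strand = !stranded)
  list(
    recall = length(unique(S4Vectors::subjectHits(ov))) / nrow(truth),
    precision = length(unique(S4Vectors::queryHits(ov))) / nrow(peaks),
    n_peaks = nrow(peaks), n_truth = nrow(truth)
  )
}
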