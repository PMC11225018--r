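base_count_matrix <- function(sequence) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  code <- match(v, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    stop("non-IUPAC character in sequence: ",
         paste(unique(v[is.na(code)]), collapse = ", "))
  }
  code
}

skew_from_counts <- function(a, b) {
  tot <- a + b
  ifelse(tot == 0, NA_real_, (a - b) / tot)
}

#' GC and AT skew of a sequence
#'
#' `gc_skew = (G - C)/(G + C)` and `at_skew = (A - T)/(A + T)`, counted on
#' the Watson strand as written; `N` bases are ignored. When the
#' denominator is zero the skew is undefined and returned as `NA` (never
#' 0, which is a meaningful "balanced" value). Vectorized over character
#' vectors.
#'
#' @param sequence character vector of sequences over `A,C,G,T,N`.
#' @return numeric vector of skews in `[-1, 1]` or `NA`.
#' @export
gc_skew <- function(sequence) {
  vapply(sequence, function(s) {
    code <- base_count_matrix(s)
    skew_from_counts(sum(code == 3L), sum(code == 2L))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname gc_skew
#' @export
at_skew <- function(sequence) {
  vapply(sequence, function(s) {
    code <- base_count_matrix(s)
    skew_from_counts(sum(code == 1L), sum(code == 4L))
  }, numeric(1), USE.NAMES = FALSE)
}

# cumulative base counts for O(1) window queries; col i = count in [0, i)
cum_base_counts <- function(sequence) {
  code <- base_count_matrix(sequence)
  list(
    A = cumsum(code == 1L), C = cumsum(code == 2L),
    G = cumsum(code == 3L), T = cumsum(code == 4L)
  )
}

window_counts <- function(cum, starts, ends) {
  # counts of each base in [start, end), 0-based
  g <- function(v) {
    lo <- numeric(length(starts))
    nz <- starts > 0L
    lo[nz] <- v[starts[nz]]
    v[ends] - lo
  }
  list(A = g(cum$A), C = g(cum$C), G = g(cum$G), T = g(cum$T))
}

#' Sliding-window skew track
#'
#' Windows start at 0, `step`, 2*`step`, ... with the full window inside
#' the chromosome; each reports GC and AT skew, anchored at the window
#' midpoint. Defaults follow the field's convention of a 200 bp window
#' with a 50 bp step.
#'
#' @param genome a `GenomeRef` with sequences.
#' @param window window size in bases (default 200).
#' @param step step between window starts (default 50).
#' @param chroms chromosomes to scan (default: all with sequence).
#' @return data frame (`chrom`, `start`, `end`, `mid`, `gc_skew`,
#'   `at_skew`), one row per window.
#' @export
skew_track <- function(genome, window = 200, step = 50,
                       chroms = genome$chrom_names) {
  stopifnot(window >= 1, step >= 1)
  out <- lapply(chroms, function(ch) {
    len <- genome$chrom_lengths[[ch]]
    if (window > len) {
      warning("window larger than chromosome ", ch, "; no windows emitted")
      return(NULL)
    }
    starts <- seq.int(0L, len - window, by = step)
    cum <- cum_base_counts(genome_sequence(genome, ch))
    cnt <- window_counts(cum, starts, starts + window)
    data.frame(
      chrom = ch, start = starts, end = starts + window,
      mid = starts + window %/% 2,
      gc_skew = skew_from_counts(cnt$G, cnt$C),
      at_skew = skew_from_counts(cnt$A, cnt$T)
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Skew metaprofile around a region set
#'
#' Each region is anchored at its midpoint with `flank` bases on either
#' side, divided into `n_bins` bins; each bin's GC and AT skew is computed
#' from its base counts. With `strand_aware = TRUE`, `-` (cR-loop) regions
#' are reverse-complement-oriented — bin order reversed and skew sign
#' flipped — so that a cR-loop peak with mirrored skew contributes with
#' the same sign as a wR-loop peak. Regions whose window leaves the
#' chromosome are skipped and counted. Per-bin means ignore undefined
#' (`NA`) bins.
#'
#' @param genome a `GenomeRef` with sequences.
#' @param regions a non-empty `RegionSet`.
#' @param flank half-width of the window around each midpoint (bases).
#' @param n_bins number of bins across the `2*flank` window.
#' @param strand_aware orient `-` regions (default `TRUE`).
#' @return list: `profile` (per-bin mean skews with bin centers relative
#'   to the region midpoint), `gc_matrix`/`at_matrix` (region x bin), and
#'   `skipped`.
#' @export
skew_metaprofile <- function(genome, regions, flank = 1000, n_bins = 40,
                             strand_aware = TRUE) {
  if (nrow(regions) == 0L) stop("empty region set")
  stopifnot(flank >= 1, n_bins >= 1)
  edges <- round(seq(0, 2 * flank, length.out = n_bins + 1L))
  gc_mat <- matrix(NA_real_, nrow(regions), n_bins)
  at_mat <- matrix(NA_real_, nrow(regions), n_bins)
  skipped <- 0L
  cums <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    mid <- (regions$start[i] + regions$end[i]) %/% 2
    a <- mid - flank
    if (a < 0 || mid + flank > genome$chrom_lengths[[ch]]) {
      skipped <- skipped + 1L
      next
    }
    if (is.null(cums[[ch]])) cums[[ch]] <- cum_base_counts(genome_sequence(genome, ch))
    starts <- a + edges[-length(edges)]
    ends <- a + edges[-1L]
    cnt <- window_counts(cums[[ch]], starts, ends)
    gs <- skew_from_counts(cnt$G, cnt$C)
    as_ <- skew_from_counts(cnt$A, cnt$T)
    if (strand_aware && regions$strand[i] == "-") {
      gs <- -rev(gs)
      as_ <- -rev(as_)
    }
    gc_mat[i, ] <- gs
    at_mat[i, ] <- as_
  }
  centers <- (edges[-1L] + edges[-length(edges)]) / 2 - flank
  list(
    profile = data.frame(
      bin = seq_len(n_bins), center = centers,
      gc_skew = colMeans(gc_mat, na.rm = TRUE),
      at_skew = colMeans(at_mat, na.rm = TRUE)
    ),
    gc_matrix = gc_mat, at_matrix = at_mat, skipped = skipped
  )
}
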