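union_intervals <- function(start, end) {
  # union-merge of [start, end) pairs; returns list(start, end), sorted
  o <- order(start)
  start <- start[o]
  end <- cummax(end[o])
  new_grp <- c(TRUE, start[-1L] > end[-length(end)])
  first <- which(new_grp)
  last <- c(first[-1L] - 1L, length(start))
  list(start = start[first], end = end[last])
}

#' Permutation test of region-set overlap enrichment
#'
#' The observed statistic is the number of query regions overlapping at
#' least one reference region. Each permutation re-places every query
#' region uniformly at random on its own chromosome, preserving its
#' length (no inter-chromosome moves; placed regions may overlap each
#' other). The p-value uses the standard permutation estimator
#' `p = (1 + #{permuted >= observed}) / (n_perm + 1)` for enrichment
#' (`<=` for depletion), and `z = (observed - mean) / sd` over the
#' permuted statistics.
#'
#' @param query,reference `RegionSet`s.
#' @param genome a `GenomeRef` (chromosome lengths for placement).
#' @param n_perm number of permutations (>= 100).
#' @param alternative `"enrichment"` or `"depletion"`.
#' @param seed RNG seed (optional).
#' @return object of class `rloop_permtest`: observed count, permuted
#'   mean/sd, `z`, `p`, and the permuted statistics.
#' @export
overlap_permutation_test <- function(query, reference, genome,
                                     n_perm = 999,
                                     alternative = c("enrichment",
                                                     "depletion"),
                                     seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (nrow(query) == 0L) stop("empty query set")
  if (!is.null(seed)) set.seed(seed)
  qlen <- query$end - query$start
  clen <- genome$chrom_lengths[query$chrom]
  if (any(qlen > clen)) {
    stop("query region longer than its chromosome: ",
         query$chrom[which(qlen > clen)[1L]])
  }
  ref_by_chr <- split(seq_len(nrow(reference)), reference$chrom)

  hit_mat <- matrix(FALSE, nrow(query), n_perm)
  obs_hit <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    ch <- query$chrom[i]
    L <- qlen[i]
    ri <- ref_by_chr[[ch]]
    max_start <- clen[i] - L
    starts <- floor(stats::runif(n_perm) * (max_start + 1))
    if (is.null(ri) || !length(ri)) {
      obs_hit[i] <- FALSE
      next
    }
    rs <- reference$start[ri]
    re <- reference$end[ri]
    obs_hit[i] <- any(query$start[i] < re & query$end[i] > rs)
    # a placement at s overlaps some reference iff s in [rs - L + 1, re - 1]
    u <- union_intervals(pmax(rs - L + 1, 0), re)
    k <- findInterval(starts, u$start)
    hit_mat[i, ] <- k > 0L & starts <= u$end[pmax(k, 1L)] - 1
  }
  perm_stat <- colSums(hit_mat)
  observed <- sum(obs_hit)
  if (alternative == "enrichment") {
    p <- (1 + sum(perm_stat >= observed)) / (n_perm + 1)
  } else {
    p <- (1 + sum(perm_stat <= observed)) / (n_perm + 1)
  }
  sd_perm <- stats::sd(perm_stat)
  structure(
    list(
      observed = observed, n_query = nrow(query),
      perm_mean = mean(perm_stat), perm_sd = sd_perm,
      z = if (sd_perm > 0) (observed - mean(perm_stat)) / sd_perm else NA_real_,
      p = p, alternative = alternative, n_perm = n_perm,
      perm_stats = perm_stat
    ),
    class = "rloop_permtest"
  )
}

#' @export
print.rloop_permtest <- function(x, ...) {
  cat("Region-overlap permutation test (", x$alternative, ")\n", sep = "")
  cat(sprintf("  observed: %d of %d query regions overlap the reference\n",
              x$observed, x$n_query))
  cat(sprintf("  permuted: mean %.2f, sd %.2f (%d permutations)\n",
              x$perm_mean, x$perm_sd, x$n_perm))
  cat(sprintf("  z = %.3f, p = %.4g\n", x$z, x$p))
  invisible(x)
}

#' Length- and chromosome-matched random regions
#'
#' Re-places each input region uniformly at random on its own chromosome,
#' preserving its length — the matched control used for boundary and
#' signal comparisons. The output length distribution equals the input's
#' exactly (as a multiset per chromosome).
#'
#' @param regions a `RegionSet`.
#' @param genome a `GenomeRef`.
#' @param seed RNG seed (optional).
#' @return a `RegionSet` of the same size.
#' @export
matched_random_regions <- function(regions, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- regions$end - regions$start
  clen <- genome$chrom_lengths[regions$chrom]
  if (any(len > clen)) stop("region longer than its chromosome")
  start <- floor(stats::runif(nrow(regions)) * (clen - len + 1))
  region_set(regions$chrom, start, start + len, name = regions$name,
             score = regions$score, strand = regions$strand)
}
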