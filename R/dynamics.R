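#' Region-by-stage signal matrix for dynamics clustering
#'
#' Merges the per-stage peak sets into one total peak set (interval
#' union-merge, strand-blind) and fills a matrix of mean normalized
#' coverage per merged region and stage. Rows can be standardized to
#' mean 0 and population sd 1 — the scale on which stage *profiles*
#' rather than absolute levels are compared; zero-variance rows are
#' dropped and counted.
#'
#' @param tracks named list of `SignalTrack`s (final-normalization-factor
#'   scaled), one per stage, sharing a genome.
#' @param peak_sets list of per-stage `RegionSet`s.
#' @param standardize z-score rows with population sd (default `TRUE`).
#' @return object of class `StageMatrix`: `regions`, `stages`, `values`
#'   matrix, `standardized` flag, `dropped` row count.
#' @export
build_stage_matrix <- function(tracks, peak_sets, standardize = TRUE) {
  stopifnot(length(tracks) >= 2, is.list(peak_sets))
  if (is.null(names(tracks))) names(tracks) <- paste0("stage", seq_along(tracks))
  all_peaks <- do.call(rbind, lapply(peak_sets, function(p) {
    as.data.frame(p)[c("chrom", "start", "end", "name", "score", "strand")]
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0L) stop("empty total peak set")
  total <- merge_regions(as_region_set(all_peaks))
  vals <- vapply(tracks, function(tr) region_mean_coverage(tr, total),
                 numeric(nrow(total)))
  vals <- matrix(vals, nrow = nrow(total),
                 dimnames = list(total$name, names(tracks)))
  rownames(vals) <- sprintf("region_%d", seq_len(nrow(total)))
  dropped <- 0L
  if (standardize) {
    mu <- rowMeans(vals)
    sdp <- sqrt(rowMeans((vals - mu)^2))
    keep <- sdp > 0 & !is.na(sdp)
    dropped <- sum(!keep)
    total <- total[keep, , drop = FALSE]
    class(total) <- c("RegionSet", "data.frame")
    vals <- (vals[keep, , drop = FALSE] - mu[keep]) / sdp[keep]
  }
  structure(
    list(regions = total, stages = names(tracks), values = vals,
         standardized = standardize, dropped = dropped),
    class = "StageMatrix"
  )
}

#' @export
print.StageMatrix <- function(x, ...) {
  cat(sprintf("StageMatrix: %d region(s) x %d stage(s)%s, %d dropped\n",
              nrow(x$values), length(x$stages),
              if (x$standardized) " (row-standardized)" else "", x$dropped))
  invisible(x)
}

standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sdp <- sqrt(rowMeans((x - mu)^2))
  (x - mu) / sdp
}

fcm_memberships <- function(d2, m) {
  # U_ik from squared distances; exact membership for coincident centers
  n <- nrow(d2)
  u <- matrix(0, n, ncol(d2))
  zero <- d2 < .Machine$double.eps
  has_zero <- rowSums(zero) > 0L
  if (any(has_zero)) {
    first0 <- apply(zero[has_zero, , drop = FALSE], 1L, which.max)
    u[cbind(which(has_zero), first0)] <- 1
  }
  if (any(!has_zero)) {
    w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    u[!has_zero, ] <- w / rowSums(w)
  }
  u
}

fcm_objective <- function(x, u, v, m) {
  d2 <- sq_dist(x, v)
  sum(u^m * d2)
}

sq_dist <- function(x, v) {
  # n x c matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * x %*% t(v)
}

#' Fuzzy c-means clustering of stage profiles
#'
#' The standard fuzzy c-means iteration on Euclidean distance:
#' centers `v_k = sum_i U_ik^m x_i / sum_i U_ik^m`, memberships
#' `U_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))`, from a seeded random
#' membership initialization, until `max |delta U| < tol` or `max_iter`.
#' A point coinciding with a center gets membership 1 to the first such
#' center. Several random restarts are run and the solution with the
#' lowest objective `J = sum U^m d^2` is kept.
#'
#' @param x a `StageMatrix` (standardized) or plain numeric matrix.
#' @param c number of clusters (default 6; >= 2).
#' @param m fuzzifier (> 1; default 2).
#' @param tol convergence threshold on memberships (default 1e-6).
#' @param max_iter iteration cap per restart.
#' @param n_start random restarts (default 5).
#' @param seed RNG seed (optional).
#' @return object of class `fuzzy_cmeans`: `centers` (c x stages),
#'   `membership` (regions x c, rows sum to 1), `hard_labels`,
#'   `objective` trace of the winning restart, `c`, `m`, `iterations`.
#' @export
fuzzy_cmeans <- function(x, c = 6, m = 2, tol = 1e-6, max_iter = 200,
                         n_start = 5, seed = NULL) {
  mat <- if (inherits(x, "StageMatrix")) x$values else as.matrix(x)
  stopifnot(c >= 2, m > 1)
  if (anyNA(mat)) stop("NaN/NA in input matrix")
  if (c > nrow(mat)) stop("more clusters than regions")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_start)) {
    u <- matrix(stats::rexp(nrow(mat) * c), nrow(mat), c)
    u <- u / rowSums(u)
    trace <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      um <- u^m
      v <- (t(um) %*% mat) / colSums(um)
      d2 <- pmax(sq_dist(mat, v), 0)
      u_new <- fcm_memberships(d2, m)
      trace <- c(trace, sum(u_new^m * d2))
      delta <- max(abs(u_new - u))
      u <- u_new
      if (delta < tol || iter >= max_iter) break
    }
    j <- trace[length(trace)]
    if (is.null(best) || j < best$objective[length(best$objective)]) {
      best <- list(u = u, v = v, objective = trace, iterations = iter)
    }
  }
  hard <- max.col(best$u, ties.method = "first")
  structure(
    list(
      centers = best$v, membership = best$u, hard_labels = hard,
      objective = best$objective, c = c, m = m,
      iterations = best$iterations,
      stages = colnames(mat), region_names = rownames(mat)
    ),
    class = "fuzzy_cmeans"
  )
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d clusters, fuzzifier m = %g, %d regions\n",
              x$c, x$m, nrow(x$membership)))
  cat("  cluster sizes (hard labels):",
      paste(tabulate(x$hard_labels, x$c), collapse = ", "), "\n")
  cat(sprintf("  objective %.4g after %d iterations\n",
              x$objective[length(x$objective)], x$iterations))
  invisible(x)
}

#' @export
summary.fuzzy_cmeans <- function(object, ...) {
  cat(sprintf("Fuzzy c-means fit (%d clusters, m = %g)\n", object$c, object$m))
  cat("Centers (stage profiles):\n")
  print(round(object$centers, 3))
  cat("Membership quartiles of the winning (hard) cluster:\n")
  win <- object$membership[cbind(seq_len(nrow(object$membership)),
                                 object$hard_labels)]
  print(stats::quantile(win))
  invisible(object)
}

#' @export
plot.fuzzy_cmeans <- function(x, ...) {
  graphics::matplot(t(x$centers), type = "b", lty = 1, pch = 16,
                    xlab = "stage", ylab = "standardized signal",
                    main = sprintf("fuzzy c-means centers (c = %d)", x$c),
                    xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ncol(x$centers)),
                 labels = x$stages %||% seq_len(ncol(x$centers)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cluster summary of a fuzzy c-means fit
#'
#' @param result a `fuzzy_cmeans` fit.
#' @param matrix the `StageMatrix` (or matrix) that was clustered.
#' @param threshold membership threshold for "core" members (default 0.5).
#' @return list: `counts` by hard label, `centers`, `core_counts`, and
#'   `core_members` (row indices per cluster).
#' @export
cluster_report <- function(result, matrix, threshold = 0.5) {
  stopifnot(inherits(result, "fuzzy_cmeans"))
  counts <- tabulate(result$hard_labels, result$c)
  win <- result$membership[cbind(seq_len(nrow(result$membership)),
                                 result$hard_labels)]
  core <- lapply(seq_len(result$c), function(k) {
    which(result$hard_labels == k & win >= threshold)
  })
  list(
    counts = counts,
    centers = result$centers,
    core_counts = lengths(core),
    core_members = core,
    threshold = threshold
  )
}
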