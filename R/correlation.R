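#' Delay-coordinate embedding of an interval series
#'
#' Maps a scalar series into m-dimensional points using the standard
#' coordinate-delay construction: point i is
#' `(x_i, x_{i+delay}, ..., x_{i+(m-1)*delay})`. A series of length N yields
#' exactly `N - (m-1)*delay` points.
#'
#' @param series An [isi_series()] or numeric vector.
#' @param m Embedding dimension (integer >= 1).
#' @param delay Embedding delay (integer >= 1, default 1: consecutive
#'   intervals).
#' @return A numeric matrix with one embedded point per row.
#' @examples
#' embed_series(c(1, 3, 4, 1, 3, 4), m = 2)
#' @export
embed_series <- function(series, m, delay = 1L) {
  x <- if (inherits(series, "isi_series")) series$intervals else
    as.numeric(series)
  m <- as.integer(m)
  delay <- as.integer(delay)
  if (m < 1L || delay < 1L) stop("`m` and `delay` must be >= 1")
  n_pts <- length(x) - (m - 1L) * delay
  if (n_pts < 1L) {
    stop("series too short for embedding dimension ", m, " at delay ", delay)
  }
  idx <- outer(seq_len(n_pts), (0:(m - 1L)) * delay, "+")
  matrix(x[idx], nrow = n_pts, ncol = m)
}

#' Distance between two embedded points
#'
#' The maximum norm (largest absolute componentwise difference) is the
#' method's working metric: it keeps the noiseless steps sharp. The
#' Euclidean norm is provided for comparison.
#'
#' @param x,y Numeric vectors of equal length.
#' @param norm `"max"` (default) or `"euclidean"`.
#' @return A single non-negative number.
#' @export
pair_distance <- function(x, y, norm = c("max", "euclidean")) {
  norm <- match.arg(norm)
  if (length(x) != length(y)) stop("points must have equal dimension")
  if (norm == "max") max(abs(x - y)) else sqrt(sum((x - y)^2))
}

#' Logarithmic radius grid for the correlation integral
#'
#' Builds an increasing grid of log10 radii stepped by `log_eps_step`,
#' anchored at the sampled pairwise distances: the grid runs from
#' `pad_decades` below the smallest strictly positive sampled distance up to
#' at least the largest sampled distance (so the correlation integral
#' saturates at 1 on the grid). The downward pad serves two purposes: the
#' jump at the smallest inter-cluster distance is resolved rather than
#' absorbed into the first sample, and for series with coincident embedded
#' points (ideal patterns) the leading plateau -- the flat stretch of
#' self-cluster mass prior to the first step -- is represented on the grid.
#' Padded radii below all sampled distances carry zero counts and are
#' dropped again by [correlation_integral()].
#'
#' The grid is additionally floored at `floor_decades` below the median
#' coordinate magnitude of the points: radii that far below the data scale
#' probe the microstructure of the contamination (the intra-cluster ramp of
#' a jittered series), where difference quotients rest on a handful of
#' pairs and carry no information about pattern structure. Inter-cluster
#' distances live at the scale of interval differences, well above this
#' floor.
#'
#' @param points Numeric matrix of embedded points (rows).
#' @param log_eps_step Positive increment of log10 radius (default 0.05).
#' @param n_ref Number of reference rows used to sample distances; `NULL`
#'   (default) uses all rows.
#' @param norm `"max"` or `"euclidean"`.
#' @param pad_decades Downward grid extension below the smallest positive
#'   sampled distance, in decades (default 1).
#' @param floor_decades Grid floor below the median coordinate magnitude,
#'   in decades (default 2).
#' @param seed Optional seed for reference sampling.
#' @return Increasing numeric vector of log10 radii.
#' @export
build_eps_grid <- function(points, log_eps_step = 0.05, n_ref = NULL,
                           norm = c("max", "euclidean"), pad_decades = 1,
                           floor_decades = 2, seed = NULL) {
  norm <- match.arg(norm)
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  if (log_eps_step <= 0) stop("`log_eps_step` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ref <- if (is.null(n_ref) || n_ref >= nrow(points)) seq_len(nrow(points))
         else sample.int(nrow(points), n_ref)
  rng <- .dist_range(points, as.integer(ref), if (norm == "max") 0L else 1L)
  if (!is.finite(rng[1])) {
    stop("all sampled points are identical: no positive distance to anchor ",
         "the radius grid")
  }
  lo <- grid_lo(points, rng, log_eps_step, pad_decades, floor_decades)
  hi <- log10(rng[2])
  n_up <- ceiling((hi - lo) / log_eps_step - 1e-9)
  lo + log_eps_step * (0:n_up)
}

# lower grid anchor: pad below the smallest positive distance, but never
# more than `floor_decades` below the data's own scale
grid_lo <- function(points, rng, log_eps_step, pad_decades, floor_decades) {
  lo <- log10(rng[1]) - max(pad_decades, log_eps_step)
  scale_med <- stats::median(abs(points))
  if (is.finite(scale_med) && scale_med > 0) {
    lo <- max(lo, log10(scale_med) - floor_decades)
  }
  min(lo, log10(rng[2]) - log_eps_step)
}

#' Correlation integral over a logarithmic radius grid
#'
#' For each radius eps on the grid, `C(eps)` is the average over `n_ref`
#' uniformly sampled reference points (without replacement, self-pair
#' excluded) of the fraction of the other points within distance <= eps
#' (closed ball, maximum norm by default). Both axes are returned on the
#' log10 scale; `C` is non-decreasing and reaches 1 at the top of an
#' auto-built grid (see [build_eps_grid()]). Leading radii of an auto-built
#' grid whose pooled pair count falls below `min_count` are dropped: a
#' difference quotient resting on a handful of pairs is dominated by
#' counting noise and produces spurious stair-step plateaus. The number of
#' dropped radii is recorded in the `dropped` field of the result (and
#' reported when `options(loglogstep.verbose = TRUE)`).
#'
#' @param points Numeric matrix of embedded points, or an [isi_series()] /
#'   numeric vector together with `m`.
#' @param m Embedding dimension used when `points` is a series; also
#'   recorded in the result.
#' @param n_ref Number of random reference points (default 250, capped at
#'   the number of points).
#' @param log_eps_step Grid increment in log10 radius (default 0.05).
#' @param norm `"max"` (default) or `"euclidean"`.
#' @param eps_grid Optional explicit increasing vector of log10 radii,
#'   overriding the automatic grid.
#' @param pad_decades,floor_decades Downward grid pad and data-scale grid
#'   floor for the automatic grid, see [build_eps_grid()].
#' @param min_count Minimum pooled pair count for a leading auto-grid
#'   radius to be retained (default 100; not applied to a user-supplied
#'   `eps_grid`).
#' @param delay Embedding delay when `points` is a series.
#' @param seed Optional integer seed for reference-point sampling.
#' @return An object of class `correlation_curve`: list with `log_eps`,
#'   `log_C`, `m`, `n_points`, `n_ref`, `log_eps_step`, `norm`, `dropped`.
#' @export
correlation_integral <- function(points, m = NULL, n_ref = 250,
                                 log_eps_step = 0.05,
                                 norm = c("max", "euclidean"),
                                 eps_grid = NULL, pad_decades = 1,
                                 floor_decades = 2, min_count = 100,
                                 delay = 1L, seed = NULL) {
  norm <- match.arg(norm)
  if (inherits(points, "isi_series") ||
      (is.numeric(points) && is.null(dim(points)))) {
    if (is.null(m)) stop("`m` is required when `points` is a series")
    points <- embed_series(points, m = m, delay = delay)
  } else {
    points <- as.matrix(points)
    if (is.null(m)) m <- ncol(points)
  }
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 embedded points")
  if (n_ref < 1L) stop("`n_ref` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_ref <- min(as.integer(n_ref), n)
  ref <- if (n_ref == n) seq_len(n) else sample.int(n, n_ref)

  ncode <- if (norm == "max") 0L else 1L
  if (is.null(eps_grid)) {
    rng <- .dist_range(points, as.integer(ref), ncode)
    if (!is.finite(rng[1])) {
      stop("all sampled points are identical: no positive distance to ",
           "anchor the radius grid")
    }
    lo <- grid_lo(points, rng, log_eps_step, pad_decades, floor_decades)
    hi <- log10(rng[2])
    n_up <- ceiling((hi - lo) / log_eps_step - 1e-9)
    eps_grid <- lo + log_eps_step * (0:n_up)
  } else {
    if (is.unsorted(eps_grid, strictly = TRUE)) {
      stop("`eps_grid` must be strictly increasing")
    }
  }

  auto_grid <- is.null(match.call()$eps_grid)
  counts <- .corr_counts(points, as.integer(ref), as.numeric(eps_grid), ncode)
  total_pairs <- n_ref * (n - 1)
  C <- counts / total_pairs
  # for small problems the count floor falls back to 1% of all pairs so
  # tiny exact fixtures keep their full curves
  count_floor <- if (auto_grid) max(1, min(min_count, total_pairs / 100))
                 else .Machine$double.xmin
  keep <- counts >= count_floor
  keep[length(keep)] <- TRUE  # the saturated top is always meaningful
  dropped <- sum(!keep)
  if (dropped > 0L) {
    if (isTRUE(getOption("loglogstep.verbose"))) {
      message("dropping ", dropped, " leading grid radii with zero counts")
    }
    eps_grid <- eps_grid[keep]
    C <- C[keep]
  }
  structure(list(log_eps = as.numeric(eps_grid), log_C = log10(C),
                 m = as.integer(m), n_points = n, n_ref = n_ref,
                 log_eps_step = log_eps_step, norm = norm,
                 dropped = dropped),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("Correlation curve: m =", x$m, "|", x$n_points, "points |",
      x$n_ref, "reference points |", x$norm, "norm\n")
  cat(sprintf("  log10(eps) in [%.3f, %.3f] (%d samples), log10(C) in [%.3f, %.3f]\n",
              min(x$log_eps), max(x$log_eps), length(x$log_eps),
              min(x$log_C), max(x$log_C)))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(log10_eps = x$log_eps, log10_C = x$log_C, m = x$m)
}
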