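#' Level/weight ladder for step and plateau detection
#'
#' The quality criteria evaluate the derivative of the log-log correlation
#' curve against a ladder of three slope levels, each carrying a weight.
#' Sharper steps clear higher levels and earn larger weights; flatter
#' plateaus stay below tighter levels and earn larger weights.
#'
#' @param levels Three strictly increasing positive slope levels.
#' @param weights Three positive weights.
#' @return An object of class `level_weights`.
#' @export
level_weights <- function(levels, weights) {
  if (length(levels) != 3L || length(weights) != 3L) {
    stop("`levels` and `weights` must each have length 3")
  }
  if (any(levels <= 0) || is.unsorted(levels, strictly = TRUE)) {
    stop("`levels` must be strictly increasing and positive")
  }
  if (any(weights <= 0)) stop("`weights` must be positive")
  structure(list(levels = as.numeric(levels), weights = as.numeric(weights)),
            class = "level_weights")
}

#' @rdname level_weights
#' @details `default_step_levels()` is the ladder used by the peak-count
#'   criteria (a) and (b): levels (0.5, 0.8, 2) in slope units with weights
#'   (1, 2, 3), rewarding sharper steps more. The bottom level sits below
#'   the between-step slope of a mixed pattern/noise curve, the middle
#'   level just below the asymptotic background slope of the 1-dimensional
#'   noise curve (the regime in which genuine steps remain distinguishable
#'   deep into the noise-dominated range), and the top level is cleared
#'   only by near-ideal sharp steps. `default_plateau_levels()` is the
#'   ladder used by the plateau-flatness criterion (c): below-levels
#'   (0.05, 0.1, 0.2) with weights (3, 2, 1) normalized to sum 1 (a
#'   weighted average of flat-sample counts), rewarding flatter plateaus
#'   more.
#' @export
default_step_levels <- function() {
  level_weights(c(0.5, 0.8, 2), c(1, 2, 3))
}

#' @rdname level_weights
#' @export
default_plateau_levels <- function() {
  level_weights(c(0.05, 0.1, 0.2), c(3, 2, 1) / 6)
}

#' Numerical derivative of a correlation curve
#'
#' Difference quotients of log10 C with respect to log10 eps between
#' consecutive grid samples; midpoints of the grid intervals are recorded.
#' Slopes are non-negative for any valid (monotone) curve.
#'
#' @param curve A `correlation_curve` (or list with `log_eps`, `log_C`).
#' @return An object of class `derivative_curve`: list with `log_eps_mid`
#'   and `slope`.
#' @export
curve_derivative <- function(curve) {
  le <- curve$log_eps
  lc <- curve$log_C
  if (length(le) < 2L) stop("curve needs at least 2 samples")
  dx <- diff(le)
  if (any(dx <= 0)) stop("degenerate grid spacing")
  structure(list(log_eps_mid = (le[-1] + le[-length(le)]) / 2,
                 slope = diff(lc) / dx),
            class = "derivative_curve")
}

#' Count derivative peaks above a level
#'
#' A peak is a maximal contiguous run of derivative samples strictly above
#' `level`; each run corresponds to one step-like increase of the log-log
#' curve at that sharpness level. A step is a rise *between* plateaus, so a
#' run must be preceded by at least one sample at or below the level to
#' count: a rise already in progress at the lower end of the observed
#' radius range (the intra-cluster ramp of a jittered series, or the smooth
#' climb of a pure-noise curve) is not a step.
#'
#' @param deriv A `derivative_curve`.
#' @param level Positive slope threshold.
#' @return Non-negative integer count of runs.
#' @export
count_peaks <- function(deriv, level) {
  if (level <= 0) stop("`level` must be > 0")
  above <- deriv$slope > level
  if (!any(above)) return(0L)
  r <- rle(above)
  sum(r$values) - as.integer(r$values[1L])
}

#' Weighted plateau count of a derivative curve
#'
#' For each below-level in the ladder, counts the derivative samples lying
#' below that level, and returns the weighted sum of the counts. With
#' weights summing to 1 (the default plateau ladder) this is the weighted
#' average count of flat samples.
#'
#' @param deriv A `derivative_curve`.
#' @param lw A [level_weights()]; default [default_plateau_levels()].
#' @param span Optional `c(lo, hi)` restricting the count to midpoints
#'   within `[lo, hi]` (used to compare curves on a common grid span).
#' @return A single non-negative number.
#' @export
plateau_count <- function(deriv, lw = default_plateau_levels(), span = NULL) {
  sl <- deriv$slope
  if (!is.null(span)) {
    keep <- deriv$log_eps_mid >= span[1] & deriv$log_eps_mid <= span[2]
    sl <- sl[keep]
  }
  sum(vapply(seq_along(lw$levels),
             function(i) lw$weights[i] * sum(sl < lw$levels[i]),
             numeric(1)))
}

# weighted quality of a 2-or-3-peak (noise-artifact) configuration at each
# ladder level; used by the surrogate branch of criterion (a)
multi_peak_quality <- function(deriv, lw) {
  vapply(seq_along(lw$levels), function(i) {
    k <- count_peaks(deriv, lw$levels[i])
    if (k >= 2L && k <= 3L) lw$weights[i] else 0
  }, numeric(1))
}

#' Criterion (a): visibility of a single step at m = p
#'
#' At embedding dimension m = p a noiseless pattern of length p produces
#' exactly one step, so the first term rewards, level by level, the
#' detection of exactly one derivative peak with the level's weight. Noise
#' can re-create the theoretically vanished extra steps; whenever 2 or 3
#' peaks are seen at a level, a second term is added instead: the multi-peak
#' quality of the data minus the multi-peak quality of the surrogate in
#' which the repeated steps emerge most pronouncedly, measuring the
#' distance of the data from the permutation null (zero when the data looks
#' like its most artifact-prone surrogate, positive when the extra steps in
#' the data are structure its surrogates do not reproduce).
#'
#' @param curve_at_p `correlation_curve` computed at m = p.
#' @param surrogate_curves List of `correlation_curve`s of permutation
#'   surrogates at the same dimension.
#' @param lw Step ladder, default [default_step_levels()].
#' @return A single score in `[-sum(w), sum(w)]`.
#' @export
criterion_a <- function(curve_at_p, surrogate_curves,
                        lw = default_step_levels()) {
  d <- curve_derivative(curve_at_p)
  peaks <- vapply(lw$levels, function(h) count_peaks(d, h), integer(1))
  score <- sum(lw$weights[peaks == 1L])
  if (any(peaks >= 2L & peaks <= 3L)) {
    if (length(surrogate_curves) == 0L) {
      stop("surrogate curves are required when 2-3 peaks are observed")
    }
    sq <- vapply(surrogate_curves,
                 function(sc) multi_peak_quality(curve_derivative(sc), lw),
                 numeric(3))
    sq <- matrix(sq, nrow = 3L)
    # the surrogate in which the repeated steps emerge most pronouncedly
    best <- sq[, which.max(colSums(sq)), drop = TRUE]
    dq <- multi_peak_quality(d, lw)
    sel <- peaks >= 2L & peaks <= 3L
    score <- score + sum(dq[sel] - best[sel])
  }
  score
}

#' Criterion (b): visibility of exactly p derivative peaks
#'
#' At the evaluation dimension (default m = 1, where the p(p-1)/2 pairwise
#' distances of a length-3 pattern reduce to three generic values) the curve
#' of a patterned series shows exactly p steps. Rewards, level by level, the
#' detection of exactly `p` peaks with the level's weight.
#'
#' @param curve `correlation_curve` at the evaluation dimension.
#' @param p Pattern length whose peak count is rewarded.
#' @param lw Step ladder, default [default_step_levels()].
#' @return A single non-negative score.
#' @export
criterion_b <- function(curve, p, lw = default_step_levels()) {
  d <- curve_derivative(curve)
  peaks <- vapply(lw$levels, function(h) count_peaks(d, h), integer(1))
  sum(lw$weights[peaks == as.integer(p)])
}

#' Criterion (c): plateau-flatness difference between consecutive dimensions
#'
#' The weighted plateau count of the curve at the higher dimension (default
#' m = p) minus that at the lower dimension (default m = p - 1), computed on
#' the common span of the two radius grids. At m = p the pattern's cluster
#' distances collapse onto fewer values, so its plateau is flatter and
#' longer than at m = p - 1; the difference persists far into the noise-
#' dominated regime.
#'
#' @param curve_hi,curve_lo `correlation_curve`s at consecutive embedding
#'   dimensions (hi = lower dimension + 1).
#' @param lw Plateau ladder, default [default_plateau_levels()].
#' @return A single number (positive when the higher dimension is flatter).
#' @export
criterion_c <- function(curve_hi, curve_lo,
                        lw = default_plateau_levels()) {
  span <- c(max(min(curve_hi$log_eps), min(curve_lo$log_eps)),
            min(max(curve_hi$log_eps), max(curve_lo$log_eps)))
  if (span[1] >= span[2]) stop("curve grids do not overlap")
  plateau_count(curve_derivative(curve_hi), lw, span = span) -
    plateau_count(curve_derivative(curve_lo), lw, span = span)
}

#' Normalize a grid of raw scores by its maximum
#'
#' Divides every entry by the grid maximum, so the best-scoring cell maps
#' to 1. Used to put the three criteria on a common scale before region
#' classification.
#'
#' @param raw Numeric vector, matrix or array of raw scores with at least
#'   one strictly positive entry.
#' @return Object of the same shape with maximum 1.
#' @export
normalize_over_grid <- function(raw) {
  mx <- max(raw, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("normalization undefined: no strictly positive score in the grid")
  }
  raw / mx
}
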