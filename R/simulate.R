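#' Jitter specification
#'
#' Describes the random perturbation added to every pattern interval. The
#' amplitude is expressed as a fraction of the smallest pattern interval, so
#' a `fraction` of 0.1 on the pattern `c(1, 3, 4)` perturbs every interval by
#' at most +/- 0.1 time units (uniform case).
#'
#' @param fraction Non-negative jitter amplitude as a fraction of the
#'   smallest pattern interval.
#' @param distribution One of `"uniform"` (default), `"gaussian"`,
#'   `"long_tailed"`. The half-width (uniform), standard deviation
#'   (gaussian) or scale parameter (long-tailed, a truncated Cauchy) equals
#'   `fraction * min(pattern)`.
#' @param signed If `TRUE` (default) perturbations are symmetric around 0,
#'   otherwise only non-negative displacements are drawn.
#' @return An object of class `jitter_spec`.
#' @export
jitter_spec <- function(fraction = 0,
                        distribution = c("uniform", "gaussian", "long_tailed"),
                        signed = TRUE) {
  distribution <- match.arg(distribution)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0) {
    stop("jitter `fraction` must be a single non-negative number")
  }
  structure(list(fraction = fraction, distribution = distribution,
                 signed = isTRUE(signed)),
            class = "jitter_spec")
}

#' Noise specification
#'
#' Describes how noise events are mixed into a patterned interval series.
#' `fraction` is the nominal per-event fraction of noise events among all
#' events. Two insertion paradigms are supported: under `"event_wise"` each
#' event independently comes from the (phase-tracked) pattern with
#' probability `1 - fraction`, otherwise from the noise distribution; under
#' `"pattern_wise"` a Bernoulli draw with the rescaled probability
#' [rescale_pattern_probability()] appends either the whole jittered pattern
#' (p events) or a single noise event, so that the expected per-event noise
#' fraction still equals `fraction`.
#'
#' Noise intervals are drawn uniformly from `(noise_min, noise_max]`; the
#' default support `(0, 1.5 * max(pattern)]` spans and exceeds the pattern's
#' own scale without introducing a new free scale parameter (`noise_max =
#' NULL` requests this default at generation time).
#'
#' @param fraction Target fraction of noise events in `[0, 1]`.
#' @param paradigm `"pattern_wise"` (default) or `"event_wise"`.
#' @param noise_min,noise_max Support of the uniform noise-interval law;
#'   `noise_max = NULL` means `1.5 * max(pattern)`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fraction = 0,
                       paradigm = c("pattern_wise", "event_wise"),
                       noise_min = 0, noise_max = NULL) {
  paradigm <- match.arg(paradigm)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("noise `fraction` must be a single number in [0, 1]")
  }
  if (noise_min < 0) stop("`noise_min` must be >= 0")
  if (!is.null(noise_max) && noise_max <= noise_min) {
    stop("`noise_max` must exceed `noise_min`")
  }
  structure(list(fraction = fraction, paradigm = paradigm,
                 noise_min = noise_min, noise_max = noise_max),
            class = "noise_spec")
}

check_pattern <- function(pattern) {
  if (!is.numeric(pattern) || length(pattern) < 2L ||
      any(!is.finite(pattern)) || any(pattern <= 0)) {
    stop("`pattern` must be a numeric vector of length >= 2 with strictly ",
         "positive intervals")
  }
  as.numeric(pattern)
}

#' Construct an ISI series object
#'
#' A light container for a sequence of strictly positive event intervals,
#' optionally with per-event provenance labels (`"pattern"` / `"noise"`) and
#' the seed used for generation.
#'
#' @param intervals Numeric vector of strictly positive intervals.
#' @param labels Optional character vector (same length) of
#'   `"pattern"`/`"noise"` labels.
#' @param seed Optional integer seed recorded for provenance.
#' @return An object of class `isi_series`.
#' @export
isi_series <- function(intervals, labels = NULL, seed = NULL) {
  if (!is.numeric(intervals) || length(intervals) == 0L) {
    stop("`intervals` must be a non-empty numeric vector")
  }
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    bad <- which(!is.finite(intervals) | intervals <= 0)[1L]
    stop("intervals must be strictly positive and finite (first offending ",
         "entry at position ", bad, ")")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(intervals)) {
      stop("`labels` must have the same length as `intervals`")
    }
    if (!all(labels %in% c("pattern", "noise"))) {
      stop("labels must be 'pattern' or 'noise'")
    }
  }
  structure(list(intervals = as.numeric(intervals), labels = labels,
                 seed = seed),
            class = "isi_series")
}

#' @export
print.isi_series <- function(x, ...) {
  cat("ISI series:", length(x$intervals), "intervals\n")
  if (!is.null(x$labels)) {
    cat("  labels:", sum(x$labels == "pattern"), "pattern /",
        sum(x$labels == "noise"), "noise\n")
  }
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  cat("  head:", paste(signif(utils::head(x$intervals, 8), 4),
                       collapse = ", "), "...\n")
  invisible(x)
}

#' @export
length.isi_series <- function(x) length(x$intervals)

#' Rescaled pattern-insertion probability
#'
#' Under the pattern-wise insertion paradigm one Bernoulli draw appends
#' either the whole pattern (p events) or a single noise event. For the
#' expected per-event noise fraction to equal the nominal fraction q, the
#' pattern-insertion probability must be rescaled to the solution of
#' `(1 - qt) / ((1 - qt) + qt * p) = q`, namely
#' `qt = (1 - q) / (1 - q + q * p)`.
#'
#' @param noise_fraction Nominal noise fraction q in `[0, 1]`.
#' @param p Pattern length (integer >= 2).
#' @return The pattern-insertion probability in `[0, 1]`.
#' @examples
#' rescale_pattern_probability(0.3, 3) # 0.4375
#' @export
rescale_pattern_probability <- function(noise_fraction, p) {
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("`noise_fraction` must lie in [0, 1]")
  }
  if (p < 2) stop("`p` must be an integer >= 2")
  (1 - noise_fraction) / (1 - noise_fraction + noise_fraction * p)
}

# one batch of jitter displacements; resampling for positivity is done by
# the caller, which knows the interval being perturbed
jitter_draw <- function(n, scale, spec) {
  if (scale == 0 || n == 0L) return(numeric(n))
  d <- switch(spec$distribution,
    uniform = if (spec$signed) stats::runif(n, -scale, scale)
              else stats::runif(n, 0, scale),
    gaussian = if (spec$signed) stats::rnorm(n, 0, scale)
               else abs(stats::rnorm(n, 0, scale)),
    long_tailed = if (spec$signed) stats::rcauchy(n, 0, scale)
                  else abs(stats::rcauchy(n, 0, scale)))
  d
}

#' Apply jitter to a set of intervals
#'
#' Each interval t is replaced by t + delta, with delta drawn from the
#' distribution named in the spec, scaled so its half-width (uniform),
#' standard deviation (gaussian) or scale parameter (long-tailed) equals
#' `jitter$fraction * min_interval`. Draws producing non-positive intervals
#' are resampled (rather than clipped) so the stated distribution shape is
#' preserved on the admissible range.
#'
#' @param intervals Numeric vector of strictly positive intervals.
#' @param jitter A [jitter_spec()].
#' @param min_interval Reference interval defining the jitter scale;
#'   defaults to `min(intervals)`. When jittering events of a patterned
#'   series pass the smallest *pattern* interval.
#' @param seed Optional integer seed.
#' @return Numeric vector of jittered, strictly positive intervals.
#' @export
apply_jitter <- function(intervals, jitter, min_interval = min(intervals),
                         seed = NULL) {
  stopifnot(inherits(jitter, "jitter_spec"))
  if (!is.null(seed)) set.seed(seed)
  scale <- jitter$fraction * min_interval
  if (scale == 0) return(intervals)
  out <- intervals + jitter_draw(length(intervals), scale, jitter)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- intervals[bad] + jitter_draw(length(bad), scale, jitter)
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("jitter resampling failed to produce positive intervals")
    }
  }
  out
}

#' Generate a patterned ISI series contaminated by jitter and noise
#'
#' Builds an event-interval series by repeated Bernoulli draws. Under the
#' pattern-wise paradigm, with the rescaled probability
#' [rescale_pattern_probability()] the whole jittered pattern (p events) is
#' appended, otherwise one noise interval; under the event-wise paradigm each
#' event independently comes from the phase-tracked pattern with probability
#' `1 - fraction` (the phase pointer advances only when a pattern event is
#' emitted), otherwise from the noise distribution. Generation stops at the
#' first completed insertion reaching at least `n_events` events; any
#' trailing excess is retained.
#'
#' @param pattern Numeric vector (length >= 2) of positive intervals
#'   defining one period of the regular signal.
#' @param jitter A [jitter_spec()]; default no jitter.
#' @param noise A [noise_spec()]; default no noise.
#' @param n_events Minimum number of events to generate.
#' @param seed Integer seed; identical seeds give identical series.
#' @return An [isi_series()] with provenance labels.
#' @examples
#' s <- generate_series(c(1, 3, 4), n_events = 6)
#' s$intervals # 1 3 4 1 3 4
#' @export
generate_series <- function(pattern, jitter = jitter_spec(0),
                            noise = noise_spec(0), n_events, seed = NULL) {
  pattern <- check_pattern(pattern)
  stopifnot(inherits(jitter, "jitter_spec"), inherits(noise, "noise_spec"))
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1) {
    stop("`n_events` must be a positive integer")
  }
  p <- length(pattern)
  if (n_events < p) stop("`n_events` must be at least the pattern length")
  if (!is.null(seed)) set.seed(seed)

  q <- noise$fraction
  noise_max <- if (is.null(noise$noise_max)) 1.5 * max(pattern) else
    noise$noise_max
  draw_noise <- function(n) stats::runif(n, noise$noise_min, noise_max)
  min_pat <- min(pattern)

  cap <- ceiling(n_events + p + 16)
  intervals <- numeric(cap)
  labels <- character(cap)
  k <- 0L
  push <- function(vals, lab) {
    n <- length(vals)
    if (k + n > length(intervals)) {
      length(intervals) <<- 2L * (k + n)
      length(labels) <<- 2L * (k + n)
    }
    intervals[(k + 1L):(k + n)] <<- vals
    labels[(k + 1L):(k + n)] <<- lab
    k <<- k + n
  }

  if (noise$paradigm == "pattern_wise") {
    qt <- rescale_pattern_probability(q, p)
    while (k < n_events) {
      if (stats::runif(1) < qt) {
        push(apply_jitter(pattern, jitter, min_interval = min_pat), "pattern")
      } else {
        push(draw_noise(1L), "noise")
      }
    }
  } else {
    phase <- 0L
    while (k < n_events) {
      if (stats::runif(1) < 1 - q) {
        push(apply_jitter(pattern[phase + 1L], jitter,
                          min_interval = min_pat), "pattern")
        phase <- (phase + 1L) %% p
      } else {
        push(draw_noise(1L), "noise")
      }
    }
  }

  isi_series(intervals[seq_len(k)], labels = labels[seq_len(k)], seed = seed)
}

#' Permutation surrogate of an ISI series
#'
#' Returns a uniformly random permutation of the intervals. The multiset of
#' interval values (hence every marginal moment) is preserved exactly while
#' any sequential pattern structure is destroyed; surrogates provide the
#' noise null for the step-quality criteria.
#'
#' @param series An [isi_series()] (or bare numeric vector).
#' @param seed Optional integer seed.
#' @return An [isi_series()] with permuted intervals (labels permuted
#'   alongside).
#' @export
make_surrogate <- function(series, seed = NULL) {
  if (is.numeric(series)) series <- isi_series(series)
  stopifnot(inherits(series, "isi_series"))
  n <- length(series$intervals)
  if (n == 0L) stop("cannot permute an empty series")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  isi_series(series$intervals[idx],
             labels = if (is.null(series$labels)) NULL else
               series$labels[idx],
             seed = seed)
}
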