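#' Deterministic per-cell seed
#'
#' Seeds for individual phase-diagram cells (and replicates within a cell)
#' are derived from the base seed and the cell indices by a fixed integer
#' hash, so any cell can be re-run independently of the sweep order.
#'
#' @param base_seed Integer base seed.
#' @param jitter_idx,noise_idx 1-based cell indices.
#' @param replicate 1-based replicate index.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
cell_seed <- function(base_seed, jitter_idx, noise_idx, replicate = 1L) {
  h <- (abs(base_seed) %% 1e6) * 16807 + jitter_idx * 104729 +
    noise_idx * 7919 + replicate * 101
  as.integer(h %% 2147483646 + 1)
}

#' All three quality criteria for one series
#'
#' Convenience wrapper: embeds the series at m = 1, p - 1 and p, computes
#' the three correlation curves, an ensemble of permutation-surrogate curves
#' at m = p, and evaluates criteria (a), (b) and (c).
#'
#' @param series An [isi_series()] or numeric vector.
#' @param p Assumed pattern length (>= 2).
#' @param n_ref Reference points per curve (default 250).
#' @param log_eps_step Radius grid increment (default 0.05).
#' @param n_surrogates Surrogate ensemble size for criterion (a)
#'   (default 5).
#' @param lw_step Step ladder for (a)/(b), default [default_step_levels()].
#' @param lw_plateau Plateau ladder for (c), default
#'   [default_plateau_levels()].
#' @param b_dim Evaluation dimension of criterion (b), default 1.
#' @param seed Optional integer seed (reference sampling and surrogate
#'   permutations).
#' @return List with elements `q_a`, `q_b`, `q_c` and the `curves` used.
#' @export
quality_scores <- function(series, p, n_ref = 250, log_eps_step = 0.05,
                           n_surrogates = 5,
                           lw_step = default_step_levels(),
                           lw_plateau = default_plateau_levels(),
                           b_dim = 1L, seed = NULL) {
  if (is.numeric(series)) series <- isi_series(series)
  p <- as.integer(p)
  if (p < 2L) stop("`p` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(2147483646L, 3L + n_surrogates)

  c_b <- correlation_integral(series, m = b_dim, n_ref = n_ref,
                              log_eps_step = log_eps_step, seed = sub[1])
  c_lo <- correlation_integral(series, m = p - 1L, n_ref = n_ref,
                               log_eps_step = log_eps_step, seed = sub[2])
  c_hi <- correlation_integral(series, m = p, n_ref = n_ref,
                               log_eps_step = log_eps_step, seed = sub[3])
  surr_curves <- lapply(seq_len(n_surrogates), function(i) {
    s <- make_surrogate(series, seed = sub[3L + i])
    correlation_integral(s, m = p, n_ref = n_ref,
                         log_eps_step = log_eps_step, seed = sub[3L + i])
  })
  list(q_a = criterion_a(c_hi, surr_curves, lw = lw_step),
       q_b = criterion_b(c_b, p, lw = lw_step),
       q_c = criterion_c(c_hi, c_lo, lw = lw_plateau),
       curves = list(b = c_b, lo = c_lo, hi = c_hi,
                     surrogates = surr_curves))
}

#' Jitter-by-noise phase-diagram sweep
#'
#' For every (jitter, noise) cell, generates `replicates` contaminated
#' series with deterministic seeds from [cell_seed()], evaluates criteria
#' (a), (b) and (c) via [quality_scores()], averages over replicates, and
#' normalizes each criterion matrix by its grid maximum. Region labels are
#' attached with [classify_regions()]: criterion (a) uses the two-region
#' mode (I/III), criteria (b) and (c) the three-region mode (I/II/III).
#'
#' @param pattern Positive interval pattern (length >= 2).
#' @param jitter_values Increasing jitter fractions in `[0, 1]`.
#' @param noise_values Increasing noise fractions in `[0, 1]`.
#' @param replicates Replicates per cell (default 20).
#' @param base_seed Integer base seed (default 1).
#' @param n_events Events per generated series (default 2000).
#' @param n_ref,log_eps_step,n_surrogates,lw_step,lw_plateau,b_dim Passed to
#'   [quality_scores()].
#' @param paradigm Noise paradigm, default `"pattern_wise"`.
#' @param average `"mean"` (default) or `"median"` across replicates.
#' @param thresholds Region thresholds `c(t_hi, t_lo)` on the normalized
#'   scale, default `c(0.66, 0.33)`.
#' @return An object of class `phase_diagram`: list with per-criterion
#'   score matrices (`scores`, rows = jitter, cols = noise), region label
#'   matrices (`regions`), a logical `flagged` matrix of failed cells, and
#'   `metadata`.
#' @export
phase_sweep <- function(pattern, jitter_values, noise_values,
                        replicates = 20, base_seed = 1, n_events = 2000,
                        n_ref = 250, log_eps_step = 0.05, n_surrogates = 5,
                        lw_step = default_step_levels(),
                        lw_plateau = default_plateau_levels(),
                        b_dim = 1L,
                        paradigm = c("pattern_wise", "event_wise"),
                        average = c("mean", "median"),
                        thresholds = c(0.66, 0.33)) {
  pattern <- check_pattern(pattern)
  paradigm <- match.arg(paradigm)
  average <- match.arg(average)
  if (length(jitter_values) == 0L || length(noise_values) == 0L) {
    stop("jitter and noise axes must be non-empty")
  }
  if (any(jitter_values < 0 | jitter_values > 1) ||
      any(noise_values < 0 | noise_values > 1)) {
    stop("jitter and noise values must lie in [0, 1]")
  }
  p <- length(pattern)
  avg <- if (average == "mean") mean else stats::median

  nj <- length(jitter_values)
  nn <- length(noise_values)
  mats <- list(a = matrix(NA_real_, nj, nn), b = matrix(NA_real_, nj, nn),
               c = matrix(NA_real_, nj, nn))
  flagged <- matrix(FALSE, nj, nn)
  for (ji in seq_len(nj)) {
    for (ni in seq_len(nn)) {
      qa <- qb <- qc <- rep(NA_real_, replicates)
      for (r in seq_len(replicates)) {
        sd <- cell_seed(base_seed, ji, ni, r)
        res <- tryCatch({
          s <- generate_series(pattern,
                               jitter = jitter_spec(jitter_values[ji]),
                               noise = noise_spec(noise_values[ni],
                                                  paradigm = paradigm),
                               n_events = n_events, seed = sd)
          quality_scores(s, p = p, n_ref = n_ref,
                         log_eps_step = log_eps_step,
                         n_surrogates = n_surrogates, lw_step = lw_step,
                         lw_plateau = lw_plateau, b_dim = b_dim,
                         seed = sd + 1L)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          flagged[ji, ni] <- TRUE
        } else {
          qa[r] <- res$q_a
          qb[r] <- res$q_b
          qc[r] <- res$q_c
        }
      }
      mats$a[ji, ni] <- avg(qa[!is.na(qa)])
      mats$b[ji, ni] <- avg(qb[!is.na(qb)])
      mats$c[ji, ni] <- avg(qc[!is.na(qc)])
    }
  }
  dn <- list(jitter = as.character(jitter_values),
             noise = as.character(noise_values))
  scores <- lapply(mats, function(mm) {
    dimnames(mm) <- dn
    normalize_over_grid(mm)
  })
  regions <- list(
    a = classify_regions(scores$a, thresholds, two_region = TRUE),
    b = classify_regions(scores$b, thresholds),
    c = classify_regions(scores$c, thresholds))
  structure(list(scores = scores, regions = regions, flagged = flagged,
                 jitter_values = jitter_values, noise_values = noise_values,
                 metadata = list(pattern = pattern, replicates = replicates,
                                 base_seed = base_seed, n_events = n_events,
                                 n_ref = n_ref, log_eps_step = log_eps_step,
                                 n_surrogates = n_surrogates,
                                 lw_step = lw_step, lw_plateau = lw_plateau,
                                 b_dim = b_dim, paradigm = paradigm,
                                 average = average,
                                 thresholds = thresholds)),
            class = "phase_diagram")
}

#' Classify normalized scores into visibility regions
#'
#' Maps normalized scores onto the visibility regimes: scores at or above
#' `thresholds[1]` are region I ("excellent"), scores in between region II
#' ("fair"), scores below `thresholds[2]` region III ("ambiguous"). In
#' `two_region` mode (criterion (a)) region II is merged into III.
#'
#' @param normalized Numeric matrix (or vector) of normalized scores.
#' @param thresholds `c(t_hi, t_lo)` with `1 > t_hi > t_lo > 0`.
#' @param two_region Merge region II into III (default `FALSE`).
#' @return A character matrix/vector of labels `"I"`, `"II"`, `"III"`.
#' @export
classify_regions <- function(normalized, thresholds = c(0.66, 0.33),
                             two_region = FALSE) {
  if (length(thresholds) != 2L || thresholds[1] <= thresholds[2] ||
      thresholds[2] <= 0 || thresholds[1] >= 1) {
    stop("`thresholds` must be c(t_hi, t_lo) with 0 < t_lo < t_hi < 1")
  }
  lab <- ifelse(normalized >= thresholds[1], "I",
                ifelse(normalized >= thresholds[2], "II", "III"))
  if (two_region) lab[lab == "II"] <- "III"
  if (is.matrix(normalized)) {
    lab <- matrix(lab, nrow = nrow(normalized),
                  dimnames = dimnames(normalized))
  }
  lab
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("Phase diagram:", length(x$jitter_values), "jitter x",
      length(x$noise_values), "noise cells,",
      x$metadata$replicates, "replicates each\n")
  cat("  pattern:", paste(x$metadata$pattern, collapse = ", "),
      "| paradigm:", x$metadata$paradigm, "\n")
  for (cr in names(x$scores)) {
    cat(sprintf("  criterion (%s): region I in %d cells, II in %d, III in %d\n",
                cr, sum(x$regions[[cr]] == "I"),
                sum(x$regions[[cr]] == "II"),
                sum(x$regions[[cr]] == "III")))
  }
  invisible(x)
}

#' Long-form data frame of a phase diagram
#'
#' @param x A `phase_diagram`.
#' @param ... Unused.
#' @return Data frame with columns `jitter`, `noise`, `criterion`,
#'   `normalized_score`, `region`.
#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$scores), function(cr) {
    grid <- expand.grid(jitter = x$jitter_values, noise = x$noise_values)
    grid$criterion <- cr
    grid$normalized_score <- as.vector(x$scores[[cr]])
    grid$region <- as.vector(x$regions[[cr]])
    grid
  }))
  rownames(out) <- NULL
  out
}
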