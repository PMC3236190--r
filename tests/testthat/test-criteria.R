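test_that("derivative is the difference quotient with recorded midpoints", {
  cv <- make_curve(c(0, 0.1, 0.2, 0.3), c(-1, -1, -0.5, -0.5))
  d <- curve_derivative(cv)
  expect_equal(d$slope, c(0, 5, 0))
  expect_equal(d$log_eps_mid, c(0.05, 0.15, 0.25))

  flat <- make_curve(seq(0, 1, 0.1), rep(0, 11))
  expect_true(all(curve_derivative(flat)$slope == 0))

  s <- generate_series(pat3, jitter = jitter_spec(0.1),
                       noise = noise_spec(0.4), n_events = 500, seed = 1)
  cc <- correlation_integral(s, m = 2, n_ref = 100, seed = 2)
  expect_true(all(curve_derivative(cc)$slope >= 0))
  expect_error(curve_derivative(make_curve(c(0, 0), c(0, 0))), "degenerate")
})

test_that("peak counting finds runs between plateaus", {
  flat <- curve_derivative(make_curve(seq(0, 1, 0.05), rep(-1, 21)))
  expect_identical(count_peaks(flat, 0.5), 0L)

  one <- curve_derivative(make_staircase(21, jump_at = 10, jump_height = 0.3))
  expect_identical(count_peaks(one, 1), 1L)

  two <- curve_derivative(make_staircase(21, jump_at = c(8, 15),
                                         jump_height = 0.3))
  expect_identical(count_peaks(two, 1), 2L)

  # a rise already in progress at the start of the grid is not a step
  ramp <- curve_derivative(make_curve(seq(0, 1, 0.05),
                                      c(seq(-2, 0, length.out = 15),
                                        rep(0, 6))))
  expect_identical(count_peaks(ramp, 0.5), 0L)
  expect_error(count_peaks(flat, 0), "> 0")
})

test_that("plateau counts are weighted, linear and span-restricted", {
  lw <- default_plateau_levels()
  d <- curve_derivative(make_curve(seq(0, 1, 0.05), rep(-1, 21)))
  expect_equal(plateau_count(d, lw), 20) # all below every level, weights sum 1

  steep <- curve_derivative(make_curve(c(0, 0.05, 0.1), c(-2, -1, 0)))
  expect_equal(plateau_count(steep, lw), 0)

  half <- level_weights(lw$levels, lw$weights / 2)
  expect_equal(plateau_count(d, half), plateau_count(d, lw) / 2)

  expect_equal(plateau_count(d, lw, span = c(0, 0.5)), 10)
})

test_that("criterion (a) is maximal for the noiseless pattern and zero-ish for noise", {
  s <- generate_series(pat3, n_events = 1500, seed = 3)
  c3 <- correlation_integral(s, m = 3, n_ref = 150, seed = 4)
  surr <- lapply(1:3, function(i) {
    su <- make_surrogate(s, seed = 10 + i)
    correlation_integral(su, m = 3, n_ref = 150, seed = 20 + i)
  })
  lw <- default_step_levels()
  expect_equal(criterion_a(c3, surr, lw), sum(lw$weights))

  noise <- generate_series(pat3, noise = noise_spec(1), n_events = 1500,
                           seed = 5)
  n3 <- correlation_integral(noise, m = 3, n_ref = 150, seed = 6)
  nsurr <- lapply(1:3, function(i) {
    su <- make_surrogate(noise, seed = 30 + i)
    correlation_integral(su, m = 3, n_ref = 150, seed = 40 + i)
  })
  expect_lt(criterion_a(n3, nsurr, lw), sum(lw$weights) / 2)
})

test_that("criterion (b) rewards exactly p peaks and vanishes degenerately", {
  s <- generate_series(pat3, n_events = 1500, seed = 7)
  c1 <- correlation_integral(s, m = 1, n_ref = 150, seed = 8)
  lw <- default_step_levels()
  expect_equal(criterion_b(c1, 3, lw), sum(lw$weights))
  # the same curve does not show 4 or 2 peaks
  expect_equal(criterion_b(c1, 4, lw), 0)
  expect_equal(criterion_b(c1, 2, lw), 0)

  flat <- make_curve(seq(0, 1, 0.05), rep(0, 21))
  expect_equal(criterion_b(flat, 3, lw), 0)
})

test_that("criterion (c) measures the flatness gain of the higher dimension", {
  cv <- make_staircase(30, jump_at = 15, jump_height = 0.4)
  expect_equal(criterion_c(cv, cv), 0)

  flatter <- make_staircase(30, jump_at = 15, jump_height = 0.4)
  steeper <- make_curve(flatter$log_eps,
                        seq(-2, 0, length.out = 30))
  expect_gt(criterion_c(flatter, steeper), 20)

  s <- generate_series(pat3, jitter = jitter_spec(0.02), n_events = 1500,
                       seed = 9)
  c3 <- correlation_integral(s, m = 3, n_ref = 150, seed = 10)
  c2 <- correlation_integral(s, m = 2, n_ref = 150, seed = 11)
  expect_gt(criterion_c(c3, c2), 0)
})

test_that("criteria are deterministic given curves and ladders", {
  s <- generate_series(pat3, jitter = jitter_spec(0.1),
                       noise = noise_spec(0.2), n_events = 800, seed = 12)
  cc <- correlation_integral(s, m = 1, n_ref = 120, seed = 13)
  expect_identical(criterion_b(cc, 3), criterion_b(cc, 3))
  q1 <- quality_scores(s, p = 3, n_ref = 120, n_surrogates = 2, seed = 14)
  q2 <- quality_scores(s, p = 3, n_ref = 120, n_surrogates = 2, seed = 14)
  expect_identical(q1[c("q_a", "q_b", "q_c")], q2[c("q_a", "q_b", "q_c")])
})

test_that("patterned series outscore their nulls at moderate contamination", {
  reps <- 20
  lw <- default_step_levels()
  qa_s <- qa_n <- qb_s <- qb_n <- numeric(reps)
  for (r in seq_len(reps)) {
    sd <- cell_seed(77, 1, 1, r)
    s <- generate_series(pat3, jitter = jitter_spec(0.1),
                         noise = noise_spec(0.3), n_events = 2000, seed = sd)
    su <- make_surrogate(s, seed = sd + 1)
    c3 <- correlation_integral(s, m = 3, n_ref = 150, seed = sd + 2)
    surr_c <- lapply(1:3, function(i) {
      z <- make_surrogate(s, seed = sd + 10 + i)
      correlation_integral(z, m = 3, n_ref = 150, seed = sd + 20 + i)
    })
    qa_s[r] <- criterion_a(c3, surr_c, lw)
    su3 <- correlation_integral(su, m = 3, n_ref = 150, seed = sd + 3)
    surr_su <- lapply(1:3, function(i) {
      z <- make_surrogate(su, seed = sd + 30 + i)
      correlation_integral(z, m = 3, n_ref = 150, seed = sd + 40 + i)
    })
    qa_n[r] <- criterion_a(su3, surr_su, lw)

    qb_s[r] <- criterion_b(correlation_integral(s, m = 1, n_ref = 150,
                                                seed = sd + 4), 3, lw)
    pure <- generate_series(pat3, noise = noise_spec(1), n_events = 2000,
                            seed = sd + 5)
    qb_n[r] <- criterion_b(correlation_integral(pure, m = 1, n_ref = 150,
                                                seed = sd + 6), 3, lw)
  }
  expect_gt(median(qa_s), median(qa_n))
  expect_gt(median(qb_s), median(qb_n))
})

test_that("peak counts are invariant under time-unit rescaling", {
  s <- generate_series(pat3, jitter = jitter_spec(0.05),
                       noise = noise_spec(0.2), n_events = 600, seed = 15)
  c1 <- correlation_integral(s, m = 1, n_ref = 150, seed = 16)
  c2 <- correlation_integral(isi_series(s$intervals * 7), m = 1,
                             n_ref = 150, seed = 16)
  for (h in default_step_levels()$levels) {
    expect_identical(count_peaks(curve_derivative(c1), h),
                     count_peaks(curve_derivative(c2), h))
  }
})

test_that("grid normalization maps the maximum to 1 and is homogeneous", {
  expect_equal(normalize_over_grid(c(2, 4)), c(0.5, 1))
  m <- matrix(c(0.2, 1, 0.5, 0.1), 2)
  expect_identical(normalize_over_grid(m), m)
  expect_equal(normalize_over_grid(3 * m), normalize_over_grid(m))
  expect_error(normalize_over_grid(c(-1, 0)), "undefined")
})
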