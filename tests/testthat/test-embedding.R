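test_that("delay embedding produces the standard coordinate-delay points", {
  e <- embed_series(c(1, 3, 4, 1, 3, 4), m = 2)
  expect_identical(e, matrix(c(1, 3, 4, 1, 3, 3, 4, 1, 3, 4), ncol = 2))

  x <- runif(20)
  expect_identical(embed_series(x, m = 1), matrix(x, ncol = 1))

  for (m in 1:4) {
    for (d in 1:3) {
      if (20 - (m - 1) * d < 1) next
      expect_identical(nrow(embed_series(x, m, d)), 20L - (m - 1L) * d)
    }
  }
  expect_error(embed_series(c(1, 2), m = 5), "too short")
})

test_that("pair distances satisfy the norm axioms and hand values", {
  expect_identical(pair_distance(c(1, 3), c(3, 4)), 2)
  expect_identical(pair_distance(c(1, 3), c(3, 4), "euclidean"), sqrt(5))
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3)
    expect_identical(pair_distance(x, y), pair_distance(y, x))
    expect_identical(pair_distance(x, x), 0)
    expect_true(pair_distance(x, y) >= abs(x[1] - y[1]))
  }
  expect_error(pair_distance(1:2, 1:3), "dimension")
})

test_that("the radius grid covers the sampled distances and is evenly stepped", {
  pts <- matrix(c(0, 0, 1, 1, 10, 10), ncol = 2, byrow = TRUE)
  g <- build_eps_grid(pts, log_eps_step = 0.05, pad_decades = 1,
                      floor_decades = 10)
  expect_lte(g[1], 0)        # reaches the smallest positive distance (1)
  expect_gte(g[length(g)], 1) # reaches the largest (10, within a step)
  expect_equal(unique(round(diff(g), 10)), 0.05)
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_error(build_eps_grid(matrix(1, 4, 2)), "identical")
})

test_that("correlation integral is monotone, saturates at 1 and matches the R oracle", {
  s <- generate_series(pat3, jitter = jitter_spec(0.1),
                       noise = noise_spec(0.2), n_events = 80, seed = 21)
  pts <- embed_series(s, m = 2)
  curve <- correlation_integral(pts, n_ref = nrow(pts), seed = 22)
  expect_true(all(diff(curve$log_C) >= 0))
  expect_identical(curve$log_C[length(curve$log_C)], 0)

  # full-pairwise plain-R oracle on the same grid
  C_oracle <- r_correlation_oracle(pts, curve$log_eps)
  expect_equal(10^curve$log_C, C_oracle, tolerance = 1e-12)

  # euclidean option agrees with its oracle too
  ce <- correlation_integral(pts, n_ref = nrow(pts), norm = "euclidean",
                             seed = 23)
  expect_equal(10^ce$log_C, r_correlation_oracle(pts, ce$log_eps, "euclidean"),
               tolerance = 1e-12)
})

test_that("two equal clusters give the exact combinatorial correlation values", {
  k <- 5
  D <- 3
  pts <- rbind(matrix(0, k, 2), matrix(D, k, 2))
  curve <- correlation_integral(pts, n_ref = 2 * k,
                                eps_grid = c(log10(D) - 0.5, log10(D)))
  expect_equal(10^curve$log_C, c((k - 1) / (2 * k - 1), 1), tolerance = 1e-12)
})

test_that("time rescaling shifts the curve horizontally and leaves log C unchanged", {
  s <- generate_series(pat3, jitter = jitter_spec(0.05),
                       noise = noise_spec(0.3), n_events = 400, seed = 31)
  c1 <- correlation_integral(s, m = 3, n_ref = 150, seed = 77)
  c2 <- correlation_integral(isi_series(s$intervals * 10), m = 3,
                             n_ref = 150, seed = 77)
  expect_equal(c2$log_eps, c1$log_eps + 1, tolerance = 1e-9)
  expect_equal(c2$log_C, c1$log_C, tolerance = 1e-12)
})

test_that("random reference subsets converge to the full-pairwise curve", {
  s <- generate_series(pat3, jitter = jitter_spec(0.1),
                       noise = noise_spec(0.3), n_events = 600, seed = 41)
  pts <- embed_series(s, m = 2)
  full <- correlation_integral(pts, n_ref = nrow(pts))
  err <- sapply(c(50, 100, 200), function(nr) {
    sub <- correlation_integral(pts, n_ref = nr, eps_grid = full$log_eps,
                                seed = nr)
    at <- match(round(sub$log_eps, 9), round(full$log_eps, 9))
    mean(abs(10^sub$log_C - 10^full$log_C[at]))
  })
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 0.005) # more references do not hurt
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(correlation_integral(matrix(1, 5, 2)), "identical")
  expect_error(correlation_integral(matrix(1:2, 1, 2)), "at least 2")
  expect_error(correlation_integral(c(1, 2, 3)), "`m` is required")
})
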