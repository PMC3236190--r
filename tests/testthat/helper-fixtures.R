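# shared fixtures: built in code, no files

# the period-three validation pattern (smallest interval 1)
pat3 <- c(1, 3, 4)

# a generic period-five pattern (no coincident componentwise distances)
pat5 <- c(0.7, 1.9, 1.1, 1.6, 0.9)

# bare correlation_curve from explicit samples, for criteria unit tests
make_curve <- function(log_eps, log_C, m = 1L) {
  structure(list(log_eps = log_eps, log_C = log_C, m = as.integer(m),
                 n_points = NA_integer_, n_ref = NA_integer_,
                 log_eps_step = diff(log_eps)[1], norm = "max",
                 dropped = 0L),
            class = "correlation_curve")
}

# piecewise-constant staircase curve: flat plateaus separated by one-sample
# jumps at the given grid indices, ending saturated at log_C = 0
make_staircase <- function(n_samples, jump_at, jump_height, step = 0.05) {
  log_eps <- step * (seq_len(n_samples) - 1)
  inc <- rep(0, n_samples)
  inc[jump_at] <- jump_height
  log_C <- cumsum(inc)
  make_curve(log_eps, log_C - log_C[n_samples])
}

# full-pairwise correlation integral in plain R: the independent oracle for
# the compiled kernel (all points as reference points, self excluded)
r_correlation_oracle <- function(points, log_grid, norm = "max") {
  points <- as.matrix(points)
  n <- nrow(points)
  C <- numeric(length(log_grid))
  for (gi in seq_along(log_grid)) {
    eps <- 10^log_grid[gi]
    cnt <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- if (norm == "max") max(abs(points[i, ] - points[j, ])) else
          sqrt(sum((points[i, ] - points[j, ])^2))
        if (d <= eps) cnt <- cnt + 1L
      }
    }
    C[gi] <- cnt / (n * (n - 1))
  }
  C
}
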