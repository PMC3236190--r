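#' Bounds on the number of observable steps in the noiseless case
#'
#' For a noiseless pattern of length p embedded in dimension m with the
#' maximum norm, the p cyclic-shift clusters produce at most `n_max` and at
#' least `n_min` distinct inter-cluster distances, hence steps in the
#' log-log correlation plot. The counts follow from decomposing the
#' componentwise-distance graph into cyclic-shift subgraphs (see
#' [decompose_shift_graph()]): the distance between clusters at shift k is a
#' sliding-window maximum of width `min(m, p)` over that subgraph's distance
#' cycle, and a cycle of length L contributes between `ceiling(L / m)` and
#' `L - m + 1` distinct window maxima. Summing over the `(p-1)/2` length-p
#' cycles (p odd), or the `(p-2)/2` length-p cycles plus the p/2-edge
#' diagonal subgraph, whose distance sequence has period p/2 (p even),
#' yields the closed forms. For m > p the values equal those at m = p:
#' windows longer than one period add no new componentwise comparisons.
#'
#' @param p Pattern length (integer >= 2).
#' @param m Embedding dimension (integer >= 1).
#' @return A one-row data frame with columns `p`, `m`, `n_min`, `n_max`.
#' @examples
#' step_bounds(3, 3) # one step
#' step_bounds(5, 5) # two steps
#' @export
step_bounds <- function(p, m) {
  p <- as.integer(p)
  m <- as.integer(m)
  if (p < 2L) stop("`p` must be an integer >= 2")
  if (m < 1L) stop("`m` must be an integer >= 1")
  me <- min(m, p)
  if (p %% 2L == 1L) {
    half <- (p - 1L) %/% 2L
    n_min <- half * ceiling(p / me)
    n_max <- half * (p - me + 1L)
  } else {
    cyc <- (p - 2L) %/% 2L
    n_min <- cyc * ceiling(p / me) + ceiling((p / 2) / me)
    n_max <- cyc * (p - me + 1L) + max(p %/% 2L - me + 1L, 1L)
  }
  data.frame(p = p, m = m, n_min = as.integer(n_min),
             n_max = as.integer(n_max))
}

#' Brute-force count of distinct inter-cluster distances
#'
#' Independent oracle for [step_bounds()]: builds the p cyclic-shift cluster
#' centers of the noiseless periodic series in dimension m, computes all
#' p(p-1)/2 pairwise maximum-norm distances, and counts the distinct values,
#' merging values closer than `tol` relative to the largest distance.
#'
#' @param pattern Numeric vector of positive intervals (length p >= 2).
#' @param m Embedding dimension.
#' @param tol Relative merge tolerance (default 1e-9 of the largest
#'   distance).
#' @return Non-negative integer count of distinct distances (= observable
#'   steps).
#' @examples
#' brute_force_step_count(c(1, 3, 4), m = 2) # 2: distances {2, 3, 3}
#' @export
brute_force_step_count <- function(pattern, m, tol = 1e-9) {
  pattern <- check_pattern(pattern)
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  if (tol <= 0) stop("`tol` must be > 0")
  p <- length(pattern)
  s <- rep(pattern, ceiling((p + m) / p) + 1L)
  centers <- embed_series(s, m = m)[seq_len(p), , drop = FALSE]
  d <- numeric(0)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      d <- c(d, max(abs(centers[i, ] - centers[j, ])))
    }
  }
  d <- sort(d)
  if (max(d) == 0) return(0L)
  sum(diff(d) > tol * max(d)) + 1L
}

#' Cyclic-shift decomposition of the componentwise-distance graph
#'
#' The unordered pairs of the p cyclic pattern positions split by shift
#' k = 1, ..., floor(p/2) into subgraphs connecting nearest, next-nearest,
#' etc. neighbors. Each shift k < p/2 gives a p-cycle (p edges); for even p
#' the final shift p/2 gives the diagonal matching with p/2 edges. The
#' subgraphs partition all p(p-1)/2 pairs and can be treated separately when
#' counting maximum-norm distances.
#'
#' @param p Pattern length (integer >= 2).
#' @return Object of class `shift_decomposition`: list with `p` and
#'   `subgraphs`, a list of 2-column matrices of position pairs (1-based),
#'   one per shift.
#' @examples
#' decompose_shift_graph(4) # a 4-cycle plus the 2-edge diagonal subgraph
#' @export
decompose_shift_graph <- function(p) {
  p <- as.integer(p)
  if (p < 2L) stop("`p` must be an integer >= 2")
  subgraphs <- lapply(seq_len(p %/% 2L), function(k) {
    if (2L * k == p) {
      cbind(from = seq_len(p %/% 2L), to = seq_len(p %/% 2L) + k)
    } else {
      cbind(from = seq_len(p), to = (seq_len(p) + k - 1L) %% p + 1L)
    }
  })
  structure(list(p = p, subgraphs = subgraphs),
            class = "shift_decomposition")
}

#' @export
print.shift_decomposition <- function(x, ...) {
  cat("Shift decomposition, p =", x$p, "\n")
  for (k in seq_along(x$subgraphs)) {
    cat("  shift", k, ":", nrow(x$subgraphs[[k]]), "edges\n")
  }
  invisible(x)
}

#' Table of step-count bounds over pattern lengths and dimensions
#'
#' Tabulates [step_bounds()] over ranges of pattern length and embedding
#' dimension, giving the reference table of lower bounds and maximally
#' observable step counts for the ideal noiseless case.
#'
#' @param p_values Integer vector of pattern lengths.
#' @param m_values Integer vector of embedding dimensions.
#' @return A data frame with columns `p`, `m`, `n_min`, `n_max`.
#' @export
bounds_table <- function(p_values, m_values) {
  if (length(p_values) == 0L || length(m_values) == 0L) {
    stop("`p_values` and `m_values` must be non-empty")
  }
  grid <- expand.grid(m = m_values, p = p_values)
  out <- do.call(rbind, Map(step_bounds, grid$p, grid$m))
  rownames(out) <- NULL
  out[, c("p", "m", "n_min", "n_max")]
}
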