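#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pooled neighbor counts for the correlation integral.
//
// For each reference point r (1-based row indices into `pts`) the distances
// to every other point are binned onto the logarithmic radius grid
// `log_grid` (log10 radii, strictly increasing). A distance d falls into the
// first grid slot j with 10^log_grid[j] >= d; the cumulative sum over slots
// then gives, per grid radius, the pooled count of (reference, other) pairs
// with d <= eps. Self-pairs are excluded. Distances above the top grid
// radius (possible only with a user-supplied grid) are dropped.
//
// norm: 0 = maximum norm, 1 = Euclidean.
// [[Rcpp::export(name = ".corr_counts")]]
NumericVector corr_counts(NumericMatrix pts, IntegerVector ref_idx,
                          NumericVector log_grid, int norm) {
  const int n = pts.nrow(), m = pts.ncol(), g = log_grid.size(),
            nref = ref_idx.size();
  const double lo = log_grid[0];
  const double step = g > 1 ? (log_grid[g - 1] - lo) / (g - 1) : 1.0;
  std::vector<double> hist(g, 0.0);
  // grid may be non-uniform when user-supplied: detect and fall back to
  // binary search in that case
  bool uniform = true;
  for (int j = 1; j < g; ++j) {
    if (std::fabs(log_grid[j] - (lo + j * step)) > 1e-9 * std::max(1.0, std::fabs(step))) {
      uniform = false;
      break;
    }
  }
  for (int a = 0; a < nref; ++a) {
    const int r = ref_idx[a] - 1;
    for (int i = 0; i < n; ++i) {
      if (i == r) continue;
      double d;
      if (norm == 0) {
        d = 0.0;
        for (int k = 0; k < m; ++k) {
          const double v = std::fabs(pts(i, k) - pts(r, k));
          if (v > d) d = v;
        }
      } else {
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          const double v = pts(i, k) - pts(r, k);
          s += v * v;
        }
        d = std::sqrt(s);
      }
      int j;
      if (d <= 0.0) {
        j = 0;  // coincident points fall inside every positive radius
      } else if (uniform) {
        const double t = (std::log10(d) - lo) / step;
        j = (int)std::ceil(t - 1e-9);
        if (j < 0) j = 0;
      } else {
        // first j with log_grid[j] >= log10(d) - tol
        const double ld = std::log10(d) - 1e-12;
        j = (int)(std::lower_bound(log_grid.begin(), log_grid.end(), ld) -
                  log_grid.begin());
      }
      if (j >= g) continue;  // beyond a user-supplied grid top
      hist[j] += 1.0;
    }
  }
  NumericVector counts(g);
  double acc = 0.0;
  for (int j = 0; j < g; ++j) {
    acc += hist[j];
    counts[j] = acc;
  }
  return counts;
}

// Pairwise distance extremes (min positive, max) over reference-point rows,
// used to anchor the radius grid without materializing the distance matrix.
// [[Rcpp::export(name = ".dist_range")]]
NumericVector dist_range(NumericMatrix pts, IntegerVector ref_idx, int norm) {
  const int n = pts.nrow(), m = pts.ncol(), nref = ref_idx.size();
  double dmin = R_PosInf, dmax = 0.0;
  for (int a = 0; a < nref; ++a) {
    const int r = ref_idx[a] - 1;
    for (int i = 0; i < n; ++i) {
      if (i == r) continue;
      double d;
      if (norm == 0) {
        d = 0.0;
        for (int k = 0; k < m; ++k) {
          const double v = std::fabs(pts(i, k) - pts(r, k));
          if (v > d) d = v;
        }
      } else {
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          const double v = pts(i, k) - pts(r, k);
          s += v * v;
        }
        d = std::sqrt(s);
      }
      if (d > 0.0 && d < dmin) dmin = d;
      if (d > dmax) dmax = d;
    }
  }
  return NumericVector::create(dmin, dmax);
}
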