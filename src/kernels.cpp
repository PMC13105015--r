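#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Smallest half-width such that the closed window [g - eps, g + eps] holds
// at least k points of the sorted vector x (saturates at the full range
// when fewer than k points exist).
static double kth_half_width(const std::vector<double>& x, double g, int k) {
  const int n = (int)x.size();
  if (n == 0) return 0.0;
  if (k > n) k = n;
  int pos = std::lower_bound(x.begin(), x.end(), g) - x.begin();
  int jlo = std::max(0, pos - k);
  int jhi = std::min(pos, n - k);
  if (jlo > n - k) jlo = n - k;
  if (jhi < jlo) jhi = jlo;
  double best = R_PosInf;
  for (int j = jlo; j <= jhi; ++j) {
    double e = std::max(g - x[j], x[j + k - 1] - g);
    if (e < best) best = e;
  }
  return best < 0 ? 0.0 : best;
}

// Adaptive symmetric-window counts for the local posterior estimator.
// sp, sb: class score vectors sorted ascending. For each grid point g the
// half-width eps is the smallest value such that the closed window
// [g - eps, g + eps] holds at least min_count pooled scores AND at least
// min_class scores of each class (each constraint saturating at the full
// range when the data run out). Counting uses binary search on the sorted
// arrays, so a full bootstrap stays cheap.
// [[Rcpp::export]]
List local_window_counts(NumericVector sp, NumericVector sb,
                         NumericVector grid, int min_count, int min_class) {
  const int nP = sp.size(), nB = sb.size(), n = nP + nB, m = grid.size();
  if (n == 0) stop("empty score sample");
  std::vector<double> pooled(n), vp(sp.begin(), sp.end()), vb(sb.begin(), sb.end());
  std::merge(sp.begin(), sp.end(), sb.begin(), sb.end(), pooled.begin());
  NumericVector eps(m);
  IntegerVector cP(m), cB(m);
  for (int i = 0; i < m; ++i) {
    const double g = grid[i];
    double best = kth_half_width(pooled, g, min_count);
    if (min_class > 0) {
      best = std::max(best, kth_half_width(vp, g, min_class));
      best = std::max(best, kth_half_width(vb, g, min_class));
    }
    eps[i] = best;
    // closed window with a relative guard against rounding at the ends
    const double tol = 1e-9 * (std::abs(g) + best + 1.0);
    const double lo = g - best - tol, hi = g + best + tol;
    cP[i] = (std::upper_bound(sp.begin(), sp.end(), hi) - sp.begin()) -
            (std::lower_bound(sp.begin(), sp.end(), lo) - sp.begin());
    cB[i] = (std::upper_bound(sb.begin(), sb.end(), hi) - sb.begin()) -
            (std::lower_bound(sb.begin(), sb.end(), lo) - sb.begin());
  }
  return List::create(_["half_width"] = eps, _["c_path"] = cP,
                      _["c_benign"] = cB);
}

// Distance-curve traversal for positive-unlabeled prior estimation.
// pos (n_pos x d) and unl (n_unl x d) are feature matrices; draws is an
// n_unl x n_reps matrix of 1-based row indices into pos (pre-drawn in R so
// all randomness stays in R's RNG). Per repetition: walk the draw column,
// find the nearest still-unconsumed unlabeled point to the drawn positive
// (Euclidean; ties broken by lowest row index), record the distance and
// consume the point, until the unlabeled copy is exhausted.
// [[Rcpp::export]]
NumericMatrix distance_curve_reps(NumericMatrix pos, NumericMatrix unl,
                                  IntegerMatrix draws) {
  const int nP = pos.nrow(), nU = unl.nrow(), d = pos.ncol();
  const int nReps = draws.ncol();
  if (draws.nrow() != nU) stop("draws must have one row per unlabeled point");
  // row-major copies for cache-friendly inner loops
  std::vector<double> P((size_t)nP * d), U((size_t)nU * d);
  for (int i = 0; i < nP; ++i)
    for (int c = 0; c < d; ++c) P[(size_t)i * d + c] = pos(i, c);
  for (int j = 0; j < nU; ++j)
    for (int c = 0; c < d; ++c) U[(size_t)j * d + c] = unl(j, c);
  NumericMatrix out(nU, nReps);
  std::vector<char> alive(nU);
  for (int r = 0; r < nReps; ++r) {
    std::fill(alive.begin(), alive.end(), 1);
    for (int t = 0; t < nU; ++t) {
      const int pi = draws(t, r) - 1;
      if (pi < 0 || pi >= nP) stop("draw index out of range");
      const double* pp = &P[(size_t)pi * d];
      double best = R_PosInf;
      int bestj = -1;
      for (int j = 0; j < nU; ++j) {
        if (!alive[j]) continue;
        const double* uu = &U[(size_t)j * d];
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = uu[c] - pp[c];
          s += diff * diff;
          if (s >= best) break;
        }
        if (s < best) { best = s; bestj = j; }
      }
      out(t, r) = std::sqrt(best);
      alive[bestj] = 0;
    }
  }
  return out;
}
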