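#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Classic dynamic time warping with absolute-difference local cost and the
// symmetric step pattern {(1,0),(0,1),(1,1)}, all steps weight 1, under an
// optional Sakoe-Chiba band. Returns the total distance and the length of
// (number of cells on) one optimal warping path, recovered by backtracking.
//
// The cumulative matrix is stored densely (n x m doubles); cells outside the
// band stay +Inf and are never visited by the DP or the backtrack.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence passed to DTW");
  const double INF = std::numeric_limits<double>::infinity();

  // Band is measured around the stretched diagonal j ~ i * m / n.
  const bool banded = band >= 0 && band < std::max(n, m);

  std::vector<double> D((size_t)n * m, INF);
  auto idx = [m](int i, int j) { return (size_t)i * m + j; };

  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (banded) {
      double diag = (double)i * (m - 1) / std::max(1, n - 1);
      jlo = std::max(0, (int)std::floor(diag) - band);
      jhi = std::min(m - 1, (int)std::ceil(diag) + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::fabs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = INF;
        if (i > 0) best = std::min(best, D[idx(i - 1, j)]);
        if (j > 0) best = std::min(best, D[idx(i, j - 1)]);
        if (i > 0 && j > 0) best = std::min(best, D[idx(i - 1, j - 1)]);
        if (best == INF) continue; // unreachable within the band
      }
      D[idx(i, j)] = cost + best;
    }
  }

  double dist = D[idx(n - 1, m - 1)];
  if (!std::isfinite(dist))
    stop("DTW band too narrow: end cell unreachable");

  // Backtrack one optimal path to count its cells (diagonal preferred on
  // ties so the path is unique and as short as possible).
  int i = n - 1, j = m - 1;
  long path_len = 1;
  while (i > 0 || j > 0) {
    double dd = (i > 0 && j > 0) ? D[idx(i - 1, j - 1)] : INF;
    double du = (i > 0) ? D[idx(i - 1, j)] : INF;
    double dl = (j > 0) ? D[idx(i, j - 1)] : INF;
    if (dd <= du && dd <= dl) {
      --i; --j;
    } else if (du <= dl) {
      --i;
    } else {
      --j;
    }
    ++path_len;
  }

  return List::create(_["distance"] = dist,
                      _["path_length"] = (double)path_len);
}
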