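#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euclidean distance between rows i and j of a column-major n x p matrix.
static inline double row_dist(const double* W, int n, int p, int i, int j) {
  double s = 0.0;
  for (int k = 0; k < p; ++k) {
    double d = W[i + (std::size_t)n * k] - W[j + (std::size_t)n * k];
    s += d * d;
  }
  return std::sqrt(s);
}

// Accumulates sum(A(Y)*A(X)), sum(A(Y)^2), sum(A(X)^2) where A(W) is the
// double-centred pairwise-distance matrix of W. Distances are recomputed in
// a second pass instead of stored, so peak memory is O(n) regardless of n.
// [[Rcpp::export(name = ".dcov_sums_cpp")]]
List dcov_sums_cpp(NumericMatrix Ym, NumericMatrix Xm) {
  const int n = Ym.nrow(), py = Ym.ncol(), px = Xm.ncol();
  const double *Y = Ym.begin(), *X = Xm.begin();
  std::vector<double> ry(n, 0.0), rx(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dy = row_dist(Y, n, py, i, j);
      const double dx = row_dist(X, n, px, i, j);
      ry[i] += dy; ry[j] += dy;
      rx[i] += dx; rx[j] += dx;
    }
  }
  double gy = 0.0, gx = 0.0;
  for (int i = 0; i < n; ++i) { gy += ry[i]; gx += rx[i]; }
  gy /= (double)n * (double)n;
  gx /= (double)n * (double)n;
  const double inv_n = 1.0 / (double)n;
  double sxy = 0.0, syy = 0.0, sxx = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ay = gy - 2.0 * ry[i] * inv_n;  // diagonal: B_ii = 0
    const double ax = gx - 2.0 * rx[i] * inv_n;
    sxy += ay * ax; syy += ay * ay; sxx += ax * ax;
    for (int j = i + 1; j < n; ++j) {
      const double ay2 = row_dist(Y, n, py, i, j)
        - (ry[i] + ry[j]) * inv_n + gy;
      const double ax2 = row_dist(X, n, px, i, j)
        - (rx[i] + rx[j]) * inv_n + gx;
      sxy += 2.0 * ay2 * ax2;
      syy += 2.0 * ay2 * ay2;
      sxx += 2.0 * ax2 * ax2;
    }
  }
  return List::create(_["sxy"] = sxy, _["syy"] = syy, _["sxx"] = sxx);
}
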