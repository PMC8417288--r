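#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-window box-counting dimension.
//
// For every pixel, a window of side `window` centred on it (clipped at the
// image borders) is tiled with axis-aligned boxes of each size in `sizes`,
// anchored at the window's top-left corner; the partial strip beyond the
// last complete box is ignored. The local dimension is the least-squares
// slope of log(occupied boxes) against log(1/box size), using the sizes
// with a non-zero count, clamped to [0, 2]. Windows with no foreground
// (and windows where fewer than two sizes yield a count) get 0.
//
// An integral image makes each box-occupancy query O(1).
// [[Rcpp::export]]
NumericMatrix local_fd_cpp(LogicalMatrix mask, int window, IntegerVector sizes) {
  const int n = mask.nrow(), m = mask.ncol();
  const int ns = sizes.size();
  std::vector<int> P((size_t)(n + 1) * (m + 1), 0);
  const int W = m + 1;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      P[(size_t)i * W + j] = (mask(i - 1, j - 1) ? 1 : 0)
        + P[(size_t)(i - 1) * W + j] + P[(size_t)i * W + j - 1]
        - P[(size_t)(i - 1) * W + j - 1];
  const int h = window / 2;
  std::vector<double> lx(ns), ly(ns);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const int r0 = std::max(0, i - h), r1 = std::min(n - 1, i + h);
      const int c0 = std::max(0, j - h), c1 = std::min(m - 1, j + h);
      const int tot = P[(size_t)(r1 + 1) * W + c1 + 1]
        - P[(size_t)r0 * W + c1 + 1] - P[(size_t)(r1 + 1) * W + c0]
        + P[(size_t)r0 * W + c0];
      if (tot == 0) { out(i, j) = 0.0; continue; }
      int k = 0;
      for (int si = 0; si < ns; ++si) {
        const int s = sizes[si];
        const int nr = (r1 - r0 + 1) / s, nc = (c1 - c0 + 1) / s;
        if (nr == 0 || nc == 0) continue;
        int cnt = 0;
        for (int a = 0; a < nr; ++a) {
          const int rr = r0 + a * s;
          for (int b = 0; b < nc; ++b) {
            const int cc = c0 + b * s;
            const int ssum = P[(size_t)(rr + s) * W + cc + s]
              - P[(size_t)rr * W + cc + s] - P[(size_t)(rr + s) * W + cc]
              + P[(size_t)rr * W + cc];
            if (ssum > 0) ++cnt;
          }
        }
        if (cnt > 0) {
          lx[k] = -std::log((double)s);
          ly[k] = std::log((double)cnt);
          ++k;
        }
      }
      if (k < 2) { out(i, j) = 0.0; continue; }
      double sx = 0, sy = 0, sxx = 0, sxy = 0;
      for (int t = 0; t < k; ++t) {
        sx += lx[t]; sy += ly[t]; sxx += lx[t] * lx[t]; sxy += lx[t] * ly[t];
      }
      const double denom = sxx - sx * sx / k;
      double slope = denom > 0 ? (sxy - sx * sy / k) / denom : 0.0;
      if (slope < 0) slope = 0; else if (slope > 2) slope = 2;
      out(i, j) = slope;
    }
  }
  return out;
}
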