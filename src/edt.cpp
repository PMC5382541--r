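#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact squared Euclidean distance transform on the pixel lattice
// (Felzenszwalb & Huttenlocher separable lower-envelope algorithm).
// For every pixel: squared distance, in pixel units, from its center to the
// center of the nearest TRUE pixel. TRUE pixels get 0; if the mask is empty
// every entry is +Inf. Squared distances between lattice points are integers,
// represented exactly in doubles, so thresholding is float-safe.
// [[Rcpp::export(name = ".edt_squared")]]
NumericMatrix edt_squared(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  const double INF = R_PosInf;

  // pass 1: per column, distance (in rows) to nearest TRUE pixel in column
  std::vector<double> g((size_t)nr * nc);
  for (int c = 0; c < nc; ++c) {
    double d = INF;
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c)) d = 0.0; else if (d < INF) d += 1.0;
      g[(size_t)r + (size_t)c * nr] = d;
    }
    d = INF;
    for (int r = nr - 1; r >= 0; --r) {
      if (mask(r, c)) d = 0.0; else if (d < INF) d += 1.0;
      size_t i = (size_t)r + (size_t)c * nr;
      if (d < g[i]) g[i] = d;
    }
  }

  // pass 2: per row, lower envelope of parabolas f(c) = g[r,c]^2
  std::vector<double> f(nc), z(nc + 1);
  std::vector<int> v(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double gg = g[(size_t)r + (size_t)c * nr];
      f[c] = (gg == INF) ? INF : gg * gg;
    }
    int k = -1;
    for (int q = 0; q < nc; ++q) {
      if (f[q] == INF) continue;
      double s = 0.0;
      if (k >= 0) {
        while (k >= 0) {
          int p = v[k];
          s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) /
              (2.0 * q - 2.0 * p);
          if (s <= z[k]) --k; else break;
        }
      }
      if (k < 0) {
        k = 0;
        v[0] = q;
        z[0] = -INF;
        z[1] = INF;
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
      }
    }
    if (k < 0) {  // no TRUE pixel anywhere on this row's column minima
      for (int c = 0; c < nc; ++c) out(r, c) = INF;
      continue;
    }
    int j = 0;
    for (int q = 0; q < nc; ++q) {
      while (z[j + 1] < q) ++j;
      int p = v[j];
      out(r, q) = (double)(q - p) * (q - p) + f[p];
    }
  }
  return out;
}
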