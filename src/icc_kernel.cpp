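#include <Rcpp.h>
using namespace Rcpp;

// Accumulate sum of squared correlations (and included-pair counts) for one
// chunk of mask voxels. z must be column-standardized to unit norm (zero
// columns encode zero-variance voxels, contributing r = 0). mode: 0 = whole
// (all j != i), 1 = short (squared world distance <= d_thr2), 2 = long
// (> d_thr2). The loop order is fixed, so results are bit-identical for any
// chunking of the voxel set.
// [[Rcpp::export(name = ".icc_chunk_kernel")]]
List icc_chunk_kernel(NumericMatrix z, IntegerVector idx, int mode,
                      NumericMatrix coords, double d_thr2) {
  const int T = z.nrow();
  const int V = z.ncol();
  const int n = idx.size();
  NumericVector sums(n);
  IntegerVector counts(n);
  const bool strat = mode != 0;

  for (int a = 0; a < n; ++a) {
    const int i = idx[a] - 1;
    const double* zi = &z(0, i);
    double s = 0.0;
    int cnt = 0;
    for (int j = 0; j < V; ++j) {
      if (j == i) continue;
      if (strat) {
        const double dx = coords(i, 0) - coords(j, 0);
        const double dy = coords(i, 1) - coords(j, 1);
        const double dz = coords(i, 2) - coords(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        const bool inc = (mode == 1) ? (d2 <= d_thr2) : (d2 > d_thr2);
        if (!inc) continue;
      }
      const double* zj = &z(0, j);
      // 4-way unrolled dot product; accumulation order is fixed at compile
      // time, so results stay bit-deterministic
      double r0 = 0.0, r1 = 0.0, r2 = 0.0, r3 = 0.0;
      int t = 0;
      for (; t + 4 <= T; t += 4) {
        r0 += zi[t] * zj[t];
        r1 += zi[t + 1] * zj[t + 1];
        r2 += zi[t + 2] * zj[t + 2];
        r3 += zi[t + 3] * zj[t + 3];
      }
      double r = (r0 + r1) + (r2 + r3);
      for (; t < T; ++t) r += zi[t] * zj[t];
      s += r * r;
      ++cnt;
    }
    sums[a] = s;
    counts[a] = cnt;
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}

// Direct-form IIR filter applied independently to each column, with zero
// initial conditions (samples before the start are taken as 0), matching a
// one-pass application of stats::filter's convolution + recursive stages.
// [[Rcpp::export(name = ".iir_filter_cols")]]
NumericMatrix iir_filter_cols(NumericVector b, NumericVector a,
                              NumericMatrix x) {
  const int T = x.nrow();
  const int V = x.ncol();
  const int nb = b.size();
  const int na = a.size();
  NumericMatrix y(T, V);
  for (int j = 0; j < V; ++j) {
    const double* xj = &x(0, j);
    double* yj = &y(0, j);
    for (int t = 0; t < T; ++t) {
      double acc = 0.0;
      const int kb = t + 1 < nb ? t + 1 : nb;
      for (int k = 0; k < kb; ++k) acc += b[k] * xj[t - k];
      const int ka = t + 1 < na ? t + 1 : na;
      for (int m = 1; m < ka; ++m) acc -= a[m] * yj[t - m];
      yj[t] = acc / a[0];
    }
  }
  return y;
}
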