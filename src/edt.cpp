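#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1-D lower-envelope passes over the three axes. Input is a
// logical/integer seed mask; output is squared distance in mm^2 given the
// isotropic voxel edge length.

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;  // index of the rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // no parabola from an unseeded column
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; continue; }  // z[0] = -INF keeps k >= 0
      break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector seed, IntegerVector dim, double h_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(N);
  for (R_xlen_t i = 0; i < N; ++i) g[i] = seed[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + sz * k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + sy * j];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[base + sy * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + sy * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + sz * k];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[base + sz * k] = d[k];
    }

  NumericVector out(N);
  double h2 = h_mm * h_mm;
  for (R_xlen_t i = 0; i < N; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : g[i] * h2;
  out.attr("dim") = dim;
  return out;
}
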