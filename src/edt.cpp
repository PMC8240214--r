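#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb & Huttenlocher 1D squared distance transform along a line of
// samples spaced s apart: d[p] = min_q f[q] + (s*(p-q))^2. Infinite entries
// of f (no source anywhere on the line yet) are skipped.
static void dt1d(const std::vector<double>& f, double s, int n,
                 std::vector<int>& idx, std::vector<int>& v,
                 std::vector<double>& z, std::vector<double>& d) {
  int m = 0;
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) idx[m++] = q;
  if (m == 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  const double s2 = s * s;
  int k = 0;
  v[0] = idx[0];
  z[0] = -INF;
  z[1] = INF;
  for (int t = 1; t < m; ++t) {
    const int q = idx[t];
    double sint;
    while (true) {
      const int p = v[k];
      sint = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
             (2.0 * s2 * (q - p));
      if (sint <= z[k]) --k; else break;  // z[0] = -inf, so k stays >= 0
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel center to the
// nearest occupied voxel center, on an anisotropic grid. Infinite where the
// mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector occ, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = occ[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax), idx(nmax);

  // x-axis (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, spacing[0], nx, idx, v, z, d);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y-axis (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, spacing[1], ny, idx, v, z, d);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // z-axis (stride nx*ny)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * nx * ny];
      dt1d(f, spacing[2], nz, idx, v, z, d);
      for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return g;
}
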