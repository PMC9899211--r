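#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact Euclidean distance transform of a 3D binary site set, computed by
// the separable lower-envelope (parabola) algorithm applied along each axis
// in turn. Distances honour anisotropic voxel spacing (mm per axis).

static const double INF = std::numeric_limits<double>::infinity();

// one-dimensional squared distance transform with sample spacing w
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double w2 = w * w;
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // no parabola at empty sites
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k]) { if (--k < 0) break; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; }
    else { ++k; v[k] = q; z[k] = s; }
    z[k + 1] = INF;
  }
  if (k < 0) {  // no sites on this scan line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
Rcpp::NumericVector edt3d_cpp(Rcpp::LogicalVector sites,
                              Rcpp::IntegerVector dim,
                              Rcpp::NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i)
    g[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int i = 0; i < ny; ++i) f[i] = g[base + (R_xlen_t)i * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int i = 0; i < ny; ++i) g[base + (R_xlen_t)i * nx] = d[i];
    }
  // pass along z
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int i = 0; i < nz; ++i) f[i] = g[base + (R_xlen_t)i * nx * ny];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int i = 0; i < nz; ++i) g[base + (R_xlen_t)i * nx * ny] = d[i];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? INF : std::sqrt(g[i]);
  return out;
}
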