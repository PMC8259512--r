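#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform, separable lower-envelope algorithm
// (Felzenszwalb & Huttenlocher 2012) generalised to anisotropic voxel
// spacing: each 1D pass minimises f(q) + a^2 (p - q)^2 with a = spacing of
// the axis being swept. BIG stands in for +infinity so parabola
// intersections stay finite.

static const double BIG = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double a) {
  const int n = (int)f.size();
  const double a2 = a * a;
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;  // sentinels are only compared, never used in arithmetic
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + a2 * q * q) - (f[p] + a2 * p * p)) / (2.0 * a2 * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = a2 * (q - p) * (double)(q - p) + f[p];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  }
  // pass along y (stride nx)
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)nx * j] = d[j];
    }
  }
  // pass along z (stride nx*ny)
  f.resize(nz); d.resize(nz);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + sxy * k];
      dt1d(f, d, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) g[base + sxy * k] = d[k];
    }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
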