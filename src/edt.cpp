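#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform along one line of samples at
// spacing `step` (lower envelope of parabolas, Felzenszwalb & Huttenlocher).
// BIG stands in for +infinity so the envelope arithmetic stays finite.
static const double BIG = 1e20;

static void dt1d(const std::vector<double>& f, int n, double step,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  const double s2 = step * step;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dd = s2 * (double)(q - p) * (q - p) + f[p];
    d[q] = dd > BIG ? BIG : dd;
  }
}

// Exact anisotropic 3-D Euclidean distance transform: distance (in mm) from
// every voxel center to the nearest voxel center with mask != 0.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<double> g((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * ((size_t)j + (size_t)ny * k);
      std::copy(g.begin() + base, g.begin() + base + nx, f.begin());
      dt1d(f, nx, spacing[0], d, v, z);
      std::copy(d.begin(), d.begin() + nx, g.begin() + base);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * ny * (size_t)k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)nx * j];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)nx * j] = d[j];
    }
  // z pass
  const size_t sxy = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + sxy * k];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) g[base + sxy * k] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = g[i] >= BIG ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
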