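#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// One box-sum pass (window 2h+1, reflect padding) along a given axis.
static void box_axis(const double *in, double *out, int nx, int ny, int nz,
                     int h, int axis) {
  if (axis == 0) {
    std::vector<double> line(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          for (int t = -h; t <= h; ++t) acc += in[base + reflect_index(i + t, nx)];
          line[i] = acc;
        }
        for (int i = 0; i < nx; ++i) out[base + i] = line[i];
      }
  } else if (axis == 1) {
    for (int z = 0; z < nz; ++z) {
      const R_xlen_t zb = (R_xlen_t)z * nx * ny;
      for (int y = 0; y < ny; ++y) {
        double *orow = out + zb + (R_xlen_t)y * nx;
        for (int i = 0; i < nx; ++i) orow[i] = 0.0;
        for (int t = -h; t <= h; ++t) {
          const double *irow = in + zb + (R_xlen_t)reflect_index(y + t, ny) * nx;
          for (int i = 0; i < nx; ++i) orow[i] += irow[i];
        }
      }
    }
  } else {
    const R_xlen_t slab = (R_xlen_t)nx * ny;
    for (int z = 0; z < nz; ++z) {
      double *oslab = out + (R_xlen_t)z * slab;
      for (R_xlen_t i = 0; i < slab; ++i) oslab[i] = 0.0;
      for (int t = -h; t <= h; ++t) {
        const double *islab = in + (R_xlen_t)reflect_index(z + t, nz) * slab;
        for (R_xlen_t i = 0; i < slab; ++i) oslab[i] += islab[i];
      }
    }
  }
}

static void box3(const double *in, double *out, double *tmp,
                 int nx, int ny, int nz, int h) {
  box_axis(in, out, nx, ny, nz, h, 0);
  box_axis(out, tmp, nx, ny, nz, h, 1);
  box_axis(tmp, out, nx, ny, nz, h, 2);
}

// Sliding-window mean, population variance and skewness (third standardized
// moment) over a cubic window of odd edge `window`, reflect padding.
// Skewness is defined as 0 where the window variance is (numerically) zero.
// [[Rcpp::export(name = ".window_moments")]]
List window_moments(NumericVector x, IntegerVector dims, int window) {
  if (window % 2 == 0 || window < 1) stop("window must be odd and positive");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != x.size()) stop("dims do not match data length");
  const int h = window / 2;
  const double nw = (double)window * window * window;

  NumericVector mu(n), va(n), sk(n);
  std::vector<double> s1(n), s2(n), s3(n), pw(n), tmp(n);
  const double *in = REAL(x);

  box3(in, s1.data(), tmp.data(), nx, ny, nz, h);
  for (R_xlen_t i = 0; i < n; ++i) pw[i] = in[i] * in[i];
  box3(pw.data(), s2.data(), tmp.data(), nx, ny, nz, h);
  for (R_xlen_t i = 0; i < n; ++i) pw[i] *= in[i];
  box3(pw.data(), s3.data(), tmp.data(), nx, ny, nz, h);

  double *pm = REAL(mu), *pv = REAL(va), *ps = REAL(sk);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double m = s1[i] / nw;
    double m2 = s2[i] / nw - m * m;
    const double m3 = s3[i] / nw - 3.0 * m * (s2[i] / nw) + 2.0 * m * m * m;
    if (m2 < 0.0) m2 = 0.0;
    pm[i] = m;
    pv[i] = m2;
    // zero-variance convention: constant windows carry no shape information
    ps[i] = (m2 <= 1e-12 * (1.0 + m * m)) ? 0.0 : m3 / std::pow(m2, 1.5);
  }
  mu.attr("dim") = dims; va.attr("dim") = dims; sk.attr("dim") = dims;
  return List::create(_["mu"] = mu, _["var"] = va, _["skew"] = sk);
}
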