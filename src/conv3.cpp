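#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Reflect (symmetric, edge-repeating) index mapping: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Separable convolution of a 3D array along one axis (0 = x/fastest, 1 = y, 2 = z)
// with a centred kernel of odd length 2r+1. Convolution convention:
//   out(i) = sum_t k(t) * in(i - t),  t = -r..r,  k stored as k[t + r].
// Boundaries are handled by reflect padding.
// [[Rcpp::export(name = ".conv3_axis")]]
NumericVector conv3_axis(NumericVector x, IntegerVector dims, NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int r = klen / 2;
  if ((R_xlen_t)nx * ny * nz != x.size()) stop("dims do not match data length");

  NumericVector out(x.size());
  const double *in = REAL(x);
  double *o = REAL(out);
  const double *k = REAL(kernel);

  if (axis == 0) {
    // contiguous axis: direct 1D convolution per line
    std::vector<double> line(nx);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          if (i >= r && i + r < nx) {
            const double *p = in + base + i;
            for (int t = -r; t <= r; ++t) acc += k[t + r] * p[-t];
          } else {
            for (int t = -r; t <= r; ++t)
              acc += k[t + r] * in[base + reflect_index(i - t, nx)];
          }
          line[i] = acc;
        }
        for (int i = 0; i < nx; ++i) o[base + i] = line[i];
      }
    }
  } else if (axis == 1) {
    // stride nx; inner loop over contiguous x for vectorization
    for (int z = 0; z < nz; ++z) {
      const R_xlen_t zb = (R_xlen_t)z * nx * ny;
      for (int y = 0; y < ny; ++y) {
        double *orow = o + zb + (R_xlen_t)y * nx;
        for (int i = 0; i < nx; ++i) orow[i] = 0.0;
        for (int t = -r; t <= r; ++t) {
          const double w = k[t + r];
          const double *irow = in + zb + (R_xlen_t)reflect_index(y - t, ny) * nx;
          for (int i = 0; i < nx; ++i) orow[i] += w * irow[i];
        }
      }
    }
  } else if (axis == 2) {
    const R_xlen_t slab = (R_xlen_t)nx * ny;
    for (int z = 0; z < nz; ++z) {
      double *oslab = o + (R_xlen_t)z * slab;
      for (R_xlen_t i = 0; i < slab; ++i) oslab[i] = 0.0;
      for (int t = -r; t <= r; ++t) {
        const double w = k[t + r];
        const double *islab = in + (R_xlen_t)reflect_index(z - t, nz) * slab;
        for (R_xlen_t i = 0; i < slab; ++i) oslab[i] += w * islab[i];
      }
    }
  } else {
    stop("axis must be 0, 1 or 2");
  }
  out.attr("dim") = dims;
  return out;
}
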