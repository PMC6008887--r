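#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form eigenvalues of a symmetric 3x3 matrix per voxel (trigonometric
// solution of the characteristic cubic). Returns the three eigenvalue fields
// sorted by signed value, lam1 >= lam2 >= lam3.
// [[Rcpp::export(name = ".eig3_sym")]]
List eig3_sym(NumericVector a11, NumericVector a22, NumericVector a33,
              NumericVector a12, NumericVector a13, NumericVector a23) {
  const R_xlen_t n = a11.size();
  NumericVector l1(n), l2(n), l3(n);
  const double *p11 = REAL(a11), *p22 = REAL(a22), *p33 = REAL(a33);
  const double *p12 = REAL(a12), *p13 = REAL(a13), *p23 = REAL(a23);
  double *e1 = REAL(l1), *e2 = REAL(l2), *e3 = REAL(l3);

  const double twopi3 = 2.0 * M_PI / 3.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x11 = p11[i], x22 = p22[i], x33 = p33[i];
    const double x12 = p12[i], x13 = p13[i], x23 = p23[i];
    const double p1 = x12 * x12 + x13 * x13 + x23 * x23;
    if (p1 == 0.0) {
      double a = x11, b = x22, c = x33, t;
      if (a < b) { t = a; a = b; b = t; }
      if (b < c) { t = b; b = c; c = t; }
      if (a < b) { t = a; a = b; b = t; }
      e1[i] = a; e2[i] = b; e3[i] = c;
      continue;
    }
    const double q = (x11 + x22 + x33) / 3.0;
    const double d11 = x11 - q, d22 = x22 - q, d33 = x33 - q;
    const double p2 = d11 * d11 + d22 * d22 + d33 * d33 + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    // det of (A - qI)/p
    const double b11 = d11 / p, b22 = d22 / p, b33 = d33 / p;
    const double b12 = x12 / p, b13 = x13 / p, b23 = x23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23)
                - b12 * (b12 * b33 - b23 * b13)
                + b13 * (b12 * b23 - b22 * b13);
    double rr = detB / 2.0;
    if (rr < -1.0) rr = -1.0;
    if (rr > 1.0) rr = 1.0;
    const double phi = std::acos(rr) / 3.0;
    const double eig1 = q + 2.0 * p * std::cos(phi);
    const double eig3 = q + 2.0 * p * std::cos(phi + twopi3);
    const double eig2 = 3.0 * q - eig1 - eig3;
    e1[i] = eig1; e2[i] = eig2; e3[i] = eig3;
  }
  if (!Rf_isNull(a11.attr("dim"))) {
    l1.attr("dim") = a11.attr("dim");
    l2.attr("dim") = a11.attr("dim");
    l3.attr("dim") = a11.attr("dim");
  }
  return List::create(_["lam1"] = l1, _["lam2"] = l2, _["lam3"] = l3);
}
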