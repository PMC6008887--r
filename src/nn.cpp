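#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal 3D kd-tree for exact nearest-neighbour queries. Ties in distance are
// broken toward the lowest reference point index so results are deterministic.

namespace {

struct KDTree {
  const double *pts; // n x 3, column-major (R matrix)
  R_xlen_t n;
  std::vector<int> idx;    // permutation of 0..n-1
  std::vector<int> axis_of; // split axis per tree node position

  double coord(int i, int ax) const { return pts[(R_xlen_t)ax * n + i]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    // pick axis with the largest spread for balance on degenerate data
    double mn[3], mx[3];
    for (int a = 0; a < 3; ++a) { mn[a] = R_PosInf; mx[a] = R_NegInf; }
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        const double c = coord(idx[i], a);
        if (c < mn[a]) mn[a] = c;
        if (c > mx[a]) mx[a] = c;
      }
    int ax = 0;
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > mx[ax] - mn[ax]) ax = a;
    const int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       const double ca = coord(a, ax), cb = coord(b, ax);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    axis_of[mid] = ax;
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(int lo, int hi, const double *q, double &bestd2, int &besti) const {
    if (hi <= lo) return;
    const int mid = (lo + hi) / 2;
    const int pi = idx[mid];
    const double dx = q[0] - coord(pi, 0);
    const double dy = q[1] - coord(pi, 1);
    const double dz = q[2] - coord(pi, 2);
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2 || (d2 == bestd2 && pi < besti)) { bestd2 = d2; besti = pi; }
    if (hi - lo == 1) return;
    const int ax = axis_of[mid];
    const double diff = q[ax] - coord(pi, ax);
    const int nearLo = diff < 0 ? lo : mid + 1;
    const int nearHi = diff < 0 ? mid : hi;
    const int farLo = diff < 0 ? mid + 1 : lo;
    const int farHi = diff < 0 ? hi : mid;
    query(nearLo, nearHi, q, bestd2, besti);
    if (diff * diff <= bestd2) query(farLo, farHi, q, bestd2, besti);
  }
};

} // namespace

// For every row of `query`, the index (1-based) of and distance to the nearest
// row of `ref` (Euclidean, exact).
// [[Rcpp::export(name = ".nn_query")]]
List nn_query_cpp(NumericMatrix ref, NumericMatrix query) {
  if (ref.ncol() != 3 || query.ncol() != 3) stop("point sets must be n x 3");
  const R_xlen_t n = ref.nrow(), m = query.nrow();
  if (n == 0) stop("reference point set is empty");

  KDTree tree;
  tree.pts = REAL(ref);
  tree.n = n;
  tree.idx.resize(n);
  tree.axis_of.assign(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) tree.idx[i] = (int)i;
  tree.build(0, (int)n, 0);

  IntegerVector out_idx(m);
  NumericVector out_d(m);
  const double *qp = REAL(query);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double q[3] = {qp[j], qp[j + m], qp[j + 2 * m]};
    double bestd2 = R_PosInf;
    int besti = (int)n; // larger than any index so ties resolve properly
    tree.query(0, (int)n, q, bestd2, besti);
    out_idx[j] = besti + 1;
    out_d[j] = std::sqrt(bestd2);
  }
  return List::create(_["index"] = out_idx, _["dist"] = out_d);
}
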