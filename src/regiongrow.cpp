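#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Union of the 26-connected components of a binary mask that contain at least
// one seed. Seeds are 0-based linear indices and must lie inside the mask.
// [[Rcpp::export(name = ".region_grow")]]
LogicalVector region_grow_cpp(IntegerVector mask, IntegerVector dims, IntegerVector seeds0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != mask.size()) stop("dims do not match mask length");

  LogicalVector out(n);
  std::vector<char> visited(n, 0);
  std::queue<R_xlen_t> q;
  const int *m = INTEGER(mask);

  for (R_xlen_t s = 0; s < seeds0.size(); ++s) {
    R_xlen_t idx = seeds0[s];
    if (idx < 0 || idx >= n) stop("seed index out of bounds");
    if (!m[idx]) stop("seed voxel is not inside the mask");
    if (!visited[idx]) { visited[idx] = 1; q.push(idx); }
  }

  while (!q.empty()) {
    const R_xlen_t idx = q.front(); q.pop();
    const int z = idx / (nx * ny);
    const int rem = idx % (nx * ny);
    const int y = rem / nx;
    const int x = rem % nx;
    for (int dz = -1; dz <= 1; ++dz) {
      const int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          const R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          if (m[nidx] && !visited[nidx]) { visited[nidx] = 1; q.push(nidx); }
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = visited[i] != 0;
  out.attr("dim") = dims;
  return out;
}
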