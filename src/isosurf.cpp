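#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by tetrahedral decomposition (marching-cubes family):
// each cell between 8 voxel centers is split into 6 tetrahedra around the main
// diagonal (Kuhn split, identical in every cell so shared faces conform and the
// surface is watertight away from the volume boundary). Surface vertices are
// linearly interpolated along tetrahedron edges and deduplicated, so the mesh
// is connected. Vertex coordinates are returned in 0-based voxel index units.

struct Key {
  uint64_t k;
  bool operator==(const Key &o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key &key) const { return std::hash<uint64_t>()(key.k); }
};

// [[Rcpp::export(name = ".iso_surface")]]
List iso_surface(NumericVector vol, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != vol.size()) stop("dims do not match data length");
  const double *v = REAL(vol);

  // local cube corner offsets, bit order x | y<<1 | z<<2
  static const int cdx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  static const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  std::vector<double> verts;           // x,y,z triplets
  std::vector<int> faces;              // 0-based vertex ids, triplets
  std::unordered_map<Key, int, KeyHash> edge_vertex;
  edge_vertex.reserve(1 << 16);

  R_xlen_t gidx[8];
  double gval[8];

  auto edge_point = [&](R_xlen_t ia, R_xlen_t ib, double va, double vb) -> int {
    if (ia > ib) { std::swap(ia, ib); std::swap(va, vb); }
    Key key{(uint64_t)ia * (uint64_t)n + (uint64_t)ib};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    const double denom = vb - va;
    const double t = (denom == 0.0) ? 0.5 : (iso - va) / denom;
    const int az = ia / (nx * ny), ar = ia % (nx * ny);
    const int bz = ib / (nx * ny), br = ib % (nx * ny);
    const double ax = ar % nx, ay = ar / nx;
    const double bx = br % nx, by = br / nx;
    verts.push_back(ax + t * (bx - ax));
    verts.push_back(ay + t * (by - ay));
    verts.push_back(az + t * (bz - az));
    const int id = (int)(verts.size() / 3) - 1;
    edge_vertex.emplace(key, id);
    return id;
  };

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const R_xlen_t idx = (R_xlen_t)(z + cdz[c]) * nx * ny +
                               (R_xlen_t)(y + cdy[c]) * nx + (x + cdx[c]);
          gidx[c] = idx;
          gval[c] = v[idx];
          (gval[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int inside[4], nin = 0, nout = 0, outv[4];
          for (int c = 0; c < 4; ++c) {
            if (gval[T[c]] > iso) inside[nin++] = T[c];
            else outv[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            const int a = (nin == 1) ? inside[0] : outv[0];
            const int *others = (nin == 1) ? outv : inside;
            const int e0 = edge_point(gidx[a], gidx[others[0]], gval[a], gval[others[0]]);
            const int e1 = edge_point(gidx[a], gidx[others[1]], gval[a], gval[others[1]]);
            const int e2 = edge_point(gidx[a], gidx[others[2]], gval[a], gval[others[2]]);
            if (e0 != e1 && e1 != e2 && e0 != e2) {
              faces.push_back(e0); faces.push_back(e1); faces.push_back(e2);
            }
          } else { // 2 in, 2 out -> quad
            const int a = inside[0], b = inside[1], c = outv[0], d = outv[1];
            const int ac = edge_point(gidx[a], gidx[c], gval[a], gval[c]);
            const int ad = edge_point(gidx[a], gidx[d], gval[a], gval[d]);
            const int bd = edge_point(gidx[b], gidx[d], gval[b], gval[d]);
            const int bc = edge_point(gidx[b], gidx[c], gval[b], gval[c]);
            if (ac != ad && ad != bd && ac != bd) {
              faces.push_back(ac); faces.push_back(ad); faces.push_back(bd);
            }
            if (ac != bd && bd != bc && ac != bc) {
              faces.push_back(ac); faces.push_back(bd); faces.push_back(bc);
            }
          }
        }
      }

  const int nv = (int)(verts.size() / 3);
  const int nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[3 * i];
    V(i, 1) = verts[3 * i + 1];
    V(i, 2) = verts[3 * i + 2];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[3 * i] + 1;     // 1-based for R
    F(i, 1) = faces[3 * i + 1] + 1;
    F(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
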