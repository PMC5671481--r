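#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra: each grid cell is split
// into six tetrahedra around the (0,0,0)-(1,1,1) diagonal (a conforming
// decomposition, so shared cell faces use the same diagonal and the mesh is
// watertight). Surface vertices sit on lattice edges at the linear
// interpolation of the iso level; triangles are oriented with normals
// pointing away from the region where value > level.

struct VKey {
  int64_t k;
  bool operator==(const VKey &o) const { return k == o.k; }
};
struct VKeyHash {
  size_t operator()(const VKey &v) const {
    return std::hash<int64_t>()(v.k);
  }
};

// [[Rcpp::export(name = ".marchingTetraCpp")]]
List marchingTetraCpp(NumericVector vol, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vol);
  const int64_t N = (int64_t)nx * ny * nz;
  std::unordered_map<VKey, int, VKeyHash> vmap;
  std::vector<double> verts; // x,y,z triplets in 0-based voxel coords
  std::vector<int> tris;     // 0-based vertex ids

  const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                            {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                          {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};

  auto lin = [&](int x, int y, int z) -> int64_t {
    return (int64_t)x + nx * ((int64_t)y + (int64_t)ny * z);
  };
  auto edgeVertex = [&](int64_t g1, int64_t g2) -> int {
    int64_t a = std::min(g1, g2), b = std::max(g1, g2);
    VKey key; key.k = a * N + b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double v1 = v[g1], v2 = v[g2];
    double t = (level - v1) / (v2 - v1);
    int x1 = (int)(g1 % nx), y1 = (int)((g1 / nx) % ny), z1 = (int)(g1 / ((int64_t)nx * ny));
    int x2 = (int)(g2 % nx), y2 = (int)((g2 / nx) % ny), z2 = (int)(g2 / ((int64_t)nx * ny));
    int id = (int)(verts.size() / 3);
    verts.push_back(x1 + t * (x2 - x1));
    verts.push_back(y1 + t * (y2 - y1));
    verts.push_back(z1 + t * (z2 - z1));
    vmap[key] = id;
    return id;
  };
  auto emit = [&](int va, int vb, int vc, const double *insideRef) {
    // orient so the normal points away from insideRef
    double *A = &verts[3 * (size_t)va], *B = &verts[3 * (size_t)vb],
           *C = &verts[3 * (size_t)vc];
    double e1[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double e2[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
    double nrm[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                     e1[2] * e2[0] - e1[0] * e2[2],
                     e1[0] * e2[1] - e1[1] * e2[0]};
    double cx = (A[0] + B[0] + C[0]) / 3 - insideRef[0];
    double cy = (A[1] + B[1] + C[1]) / 3 - insideRef[1];
    double cz = (A[2] + B[2] + C[2]) / 3 - insideRef[2];
    if (nrm[0] * cx + nrm[1] * cy + nrm[2] * cz < 0) std::swap(vb, vc);
    tris.push_back(va); tris.push_back(vb); tris.push_back(vc);
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int64_t g[8];
        double val[8];
        bool in[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          g[c] = lin(x + corner[c][0], y + corner[c][1], z + corner[c][2]);
          val[c] = v[g[c]];
          in[c] = val[c] > level;
          any = any || in[c];
          all = all && in[c];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (in[id[c]]) ins[ni++] = id[c]; else outs[no++] = id[c];
          }
          if (ni == 0 || ni == 4) continue;
          double ref[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int k2 = 0; k2 < 3; ++k2)
              ref[k2] += (double)(corner[ins[c]][k2] +
                                  (k2 == 0 ? x : (k2 == 1 ? y : z))) / ni;
          if (ni == 1) {
            int a = edgeVertex(g[ins[0]], g[outs[0]]);
            int b = edgeVertex(g[ins[0]], g[outs[1]]);
            int c2 = edgeVertex(g[ins[0]], g[outs[2]]);
            emit(a, b, c2, ref);
          } else if (ni == 3) {
            int a = edgeVertex(g[outs[0]], g[ins[0]]);
            int b = edgeVertex(g[outs[0]], g[ins[1]]);
            int c2 = edgeVertex(g[outs[0]], g[ins[2]]);
            emit(a, b, c2, ref);
          } else { // ni == 2
            int p00 = edgeVertex(g[ins[0]], g[outs[0]]);
            int p01 = edgeVertex(g[ins[0]], g[outs[1]]);
            int p10 = edgeVertex(g[ins[1]], g[outs[0]]);
            int p11 = edgeVertex(g[ins[1]], g[outs[1]]);
            emit(p00, p01, p11, ref);
            emit(p00, p11, p10, ref);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = verts[3 * (size_t)i + k];
  IntegerMatrix Tm(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int k = 0; k < 3; ++k) Tm(i, k) = tris[3 * (size_t)i + k] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = Tm);
}

// Separable Gaussian smoothing with renormalized (truncated) kernels at the
// boundary; sigma in voxels, per-axis.
// [[Rcpp::export(name = ".gaussianSmoothCpp")]]
NumericVector gaussianSmoothCpp(NumericVector vol, IntegerVector dims,
                                double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sigma <= 0) return clone(vol);
  int radius = (int)std::ceil(3 * sigma);
  std::vector<double> w(2 * radius + 1);
  for (int i = -radius; i <= radius; ++i)
    w[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
  NumericVector cur = clone(vol), nxt(vol.size());
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const double *src = REAL(cur);
    double *dst = REAL(nxt);
    const int len = n[axis];
    const R_xlen_t st = stride[axis];
    const R_xlen_t total = (R_xlen_t)nx * ny * nz;
    for (R_xlen_t idx = 0; idx < total; ++idx) {
      int pos = (int)((idx / st) % len);
      double acc = 0, norm = 0;
      int k0 = std::max(-radius, -pos), k1 = std::min(radius, len - 1 - pos);
      for (int k = k0; k <= k1; ++k) {
        acc += w[k + radius] * src[idx + (R_xlen_t)k * st];
        norm += w[k + radius];
      }
      dst[idx] = acc / norm;
    }
    std::swap(cur, nxt);
  }
  return cur;
}
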