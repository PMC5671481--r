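#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at fractional 0-based voxel
// coordinates. Points outside the grid return `fill`; `inside` reports
// whether all 8 support voxels were in bounds.
// [[Rcpp::export(name = ".trilinearCpp")]]
List trilinearCpp(NumericVector vol, IntegerVector dims, NumericMatrix pts,
                  double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  const double *v = REAL(vol);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = fill;
      inside[i] = false;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
#define V(ix, iy, iz) v[(ix) + nx * ((iy) + (R_xlen_t)ny * (iz))]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
    inside[i] = true;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Nearest-vertex search: for each query row, index (1-based) of the
// Euclidean-nearest vertex; ties broken by lowest index.
// [[Rcpp::export(name = ".nearestVertexCpp")]]
List nearestVertexCpp(NumericMatrix query, NumericMatrix verts) {
  const int nq = query.nrow(), nv = verts.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < nv; ++j) {
      double dx = verts(j, 0) - qx, dy = verts(j, 1) - qy,
             dz = verts(j, 2) - qz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bi = j;
      }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
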