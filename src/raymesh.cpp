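#include <Rcpp.h>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection for a common ray direction.
// For each origin, smallest hit parameter t >= tmin wins; t-ties go to the
// lowest triangle index. Returns t = NA for misses.
// [[Rcpp::export(name = ".rayMeshCpp")]]
List rayMeshCpp(NumericMatrix origins, NumericVector dir, NumericMatrix verts,
                IntegerMatrix tris, double tmin) {
  const int nr = origins.nrow(), nt = tris.nrow();
  NumericVector tout(nr, NA_REAL);
  IntegerVector hitTri(nr, NA_INTEGER);
  const double dx = dir[0], dy = dir[1], dz = dir[2];
  const double eps = 1e-12;
  for (int i = 0; i < nr; ++i) {
    double ox = origins(i, 0), oy = origins(i, 1), oz = origins(i, 2);
    double bestT = R_PosInf;
    int bestTri = NA_INTEGER;
    for (int k = 0; k < nt; ++k) {
      int a = tris(k, 0), b = tris(k, 1), c = tris(k, 2); // 0-based
      double v0x = verts(a, 0), v0y = verts(a, 1), v0z = verts(a, 2);
      double e1x = verts(b, 0) - v0x, e1y = verts(b, 1) - v0y,
             e1z = verts(b, 2) - v0z;
      double e2x = verts(c, 0) - v0x, e2y = verts(c, 1) - v0y,
             e2z = verts(c, 2) - v0z;
      double px = dy * e2z - dz * e2y;
      double py = dz * e2x - dx * e2z;
      double pz = dx * e2y - dy * e2x;
      double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tx = ox - v0x, ty = oy - v0y, tz = oz - v0z;
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = ty * e1z - tz * e1y;
      double qy = tz * e1x - tx * e1z;
      double qz = tx * e1y - ty * e1x;
      double w = (dx * qx + dy * qy + dz * qz) * inv;
      if (w < -1e-9 || u + w > 1 + 1e-9) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t >= tmin && t < bestT) {
        bestT = t;
        bestTri = k + 1;
      }
    }
    if (R_finite(bestT)) {
      tout[i] = bestT;
      hitTri[i] = bestTri;
    }
  }
  return List::create(_["t"] = tout, _["triangle"] = hitTri);
}

static inline void closestOnTriangle(const double *p, const double *a,
                                     const double *b, const double *c,
                                     double *out) {
  // Ericson, Real-Time Collision Detection, closest point on triangle.
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2]; return;
  }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2]; return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2]; return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Exact closest point on a triangle mesh surface for each query point.
// [[Rcpp::export(name = ".closestPointCpp")]]
NumericMatrix closestPointCpp(NumericMatrix query, NumericMatrix verts,
                              IntegerMatrix tris) {
  const int nq = query.nrow(), nt = tris.nrow();
  NumericMatrix out(nq, 3);
  for (int i = 0; i < nq; ++i) {
    double p[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best = R_PosInf, bp[3] = {p[0], p[1], p[2]};
    for (int k = 0; k < nt; ++k) {
      double a[3] = {verts(tris(k, 0), 0), verts(tris(k, 0), 1),
                     verts(tris(k, 0), 2)};
      double b[3] = {verts(tris(k, 1), 0), verts(tris(k, 1), 1),
                     verts(tris(k, 1), 2)};
      double c[3] = {verts(tris(k, 2), 0), verts(tris(k, 2), 1),
                     verts(tris(k, 2), 2)};
      double q[3];
      closestOnTriangle(p, a, b, c, q);
      double d2 = (q[0] - p[0]) * (q[0] - p[0]) +
                  (q[1] - p[1]) * (q[1] - p[1]) +
                  (q[2] - p[2]) * (q[2] - p[2]);
      if (d2 < best) {
        best = d2;
        bp[0] = q[0]; bp[1] = q[1]; bp[2] = q[2];
      }
    }
    out(i, 0) = bp[0]; out(i, 1) = bp[1]; out(i, 2) = bp[2];
  }
  return out;
}
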