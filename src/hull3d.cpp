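#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
using namespace Rcpp;

// Quickhull in 3D. Returns the hull as triangles over the original point
// set (1-based indices into `pts`), oriented outward (away from the hull
// interior). Input must contain >= 4 non-coplanar points.

struct Face {
  int a, b, c;          // 0-based point indices, outward CCW
  double n[3], d;       // plane: dot(n, x) = d, n outward (unnormalized)
  bool alive;
  std::vector<int> outside;
  int far_idx;
  double far_dist;
};

static void facePlane(const double *P, int n, Face &f) {
  const double *A = P + 3 * (R_xlen_t)f.a, *B = P + 3 * (R_xlen_t)f.b,
               *C = P + 3 * (R_xlen_t)f.c;
  double e1[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double e2[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
  f.n[0] = e1[1] * e2[2] - e1[2] * e2[1];
  f.n[1] = e1[2] * e2[0] - e1[0] * e2[2];
  f.n[2] = e1[0] * e2[1] - e1[1] * e2[0];
  f.d = f.n[0] * A[0] + f.n[1] * A[1] + f.n[2] * A[2];
  (void)n;
}

static inline double above(const double *P, const Face &f, int i) {
  const double *p = P + 3 * (R_xlen_t)i;
  double nn = std::sqrt(f.n[0] * f.n[0] + f.n[1] * f.n[1] + f.n[2] * f.n[2]);
  if (nn == 0) return 0;
  return (f.n[0] * p[0] + f.n[1] * p[1] + f.n[2] * p[2] - f.d) / nn;
}

// [[Rcpp::export(name = ".convexHullCpp")]]
List convexHullCpp(NumericMatrix ptsIn) {
  const int n = ptsIn.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  // column-major copy to row-contiguous
  std::vector<double> P(3 * (size_t)n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = ptsIn(i, k);
      P[3 * (size_t)i + k] = v;
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  double scale = std::max(hi[0] - lo[0],
                          std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (!(scale > 0)) stop("degenerate point set");
  const double eps = 1e-9 * scale;

  // initial extreme pair along x (fall back to any separated pair)
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (P[3 * (size_t)i] < P[3 * (size_t)i0]) i0 = i;
    if (P[3 * (size_t)i] > P[3 * (size_t)i1]) i1 = i;
  }
  if (i0 == i1) { i0 = 0; i1 = 1; }
  // farthest from the line i0-i1
  double best = -1; int i2 = -1;
  {
    double *A = &P[3 * (size_t)i0], *B = &P[3 * (size_t)i1];
    double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double ab2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
    for (int i = 0; i < n; ++i) {
      double *p = &P[3 * (size_t)i];
      double ap[3] = {p[0] - A[0], p[1] - A[1], p[2] - A[2]};
      double t = ab2 > 0 ? (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / ab2 : 0;
      double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1],
             dz = ap[2] - t * ab[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; i2 = i; }
    }
  }
  if (best <= eps * eps) stop("degenerate point set (collinear)");
  // farthest from the plane i0,i1,i2
  Face base; base.a = i0; base.b = i1; base.c = i2;
  facePlane(P.data(), n, base);
  best = -1; int i3 = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(above(P.data(), base, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("degenerate point set (coplanar)");

  // orient the initial tetrahedron consistently outward
  std::vector<Face> faces;
  int T[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  double ctr[3] = {0, 0, 0};
  int ids[4] = {i0, i1, i2, i3};
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j) ctr[j] += P[3 * (size_t)ids[k] + j] / 4.0;
  for (int k = 0; k < 4; ++k) {
    Face f; f.a = T[k][0]; f.b = T[k][1]; f.c = T[k][2];
    f.alive = true; f.far_idx = -1; f.far_dist = 0;
    facePlane(P.data(), n, f);
    double s = f.n[0] * ctr[0] + f.n[1] * ctr[1] + f.n[2] * ctr[2] - f.d;
    if (s > 0) { std::swap(f.b, f.c); facePlane(P.data(), n, f); }
    faces.push_back(f);
  }

  // assign outside sets
  for (int i = 0; i < n; ++i) {
    for (size_t k = 0; k < faces.size(); ++k) {
      double d = above(P.data(), faces[k], i);
      if (d > eps) {
        faces[k].outside.push_back(i);
        if (d > faces[k].far_dist) {
          faces[k].far_dist = d; faces[k].far_idx = i;
        }
        break;
      }
    }
  }

  std::vector<int> stack;
  for (size_t k = 0; k < faces.size(); ++k)
    if (!faces[k].outside.empty()) stack.push_back((int)k);

  int guard = 0;
  while (!stack.empty()) {
    if (++guard > 100 * n + 1000) stop("convex hull failed to converge");
    int fi = stack.back(); stack.pop_back();
    if (!faces[fi].alive || faces[fi].outside.empty()) continue;
    int p = faces[fi].far_idx;

    // visible set: every live face strictly facing p
    std::vector<int> visible;
    for (size_t k = 0; k < faces.size(); ++k)
      if (faces[k].alive && above(P.data(), faces[k], p) > eps)
        visible.push_back((int)k);
    if (visible.empty()) continue;

    // horizon: directed edges of visible faces not shared by two visible faces
    std::map<std::pair<int, int>, int> edgeCount;
    for (int vi : visible) {
      const Face &f = faces[vi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        int u = std::min(e[j][0], e[j][1]), v = std::max(e[j][0], e[j][1]);
        edgeCount[std::make_pair(u, v)]++;
      }
    }
    std::vector<std::pair<int, int> > horizon; // directed as in visible face
    for (int vi : visible) {
      const Face &f = faces[vi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        int u = std::min(e[j][0], e[j][1]), v = std::max(e[j][0], e[j][1]);
        if (edgeCount[std::make_pair(u, v)] == 1)
          horizon.push_back(std::make_pair(e[j][0], e[j][1]));
      }
    }

    // pool orphaned outside points, kill visible faces
    std::vector<int> pool;
    for (int vi : visible) {
      Face &f = faces[vi];
      for (int q : f.outside) if (q != p) pool.push_back(q);
      f.outside.clear();
      f.alive = false;
    }

    // new fan of faces from horizon to p
    std::vector<int> newFaces;
    for (size_t h = 0; h < horizon.size(); ++h) {
      Face f; f.a = horizon[h].first; f.b = horizon[h].second; f.c = p;
      f.alive = true; f.far_idx = -1; f.far_dist = 0;
      facePlane(P.data(), n, f);
      faces.push_back(f);
      newFaces.push_back((int)faces.size() - 1);
    }
    for (int q : pool) {
      for (int nf : newFaces) {
        double d = above(P.data(), faces[nf], q);
        if (d > eps) {
          faces[nf].outside.push_back(q);
          if (d > faces[nf].far_dist) {
            faces[nf].far_dist = d; faces[nf].far_idx = q;
          }
          break;
        }
      }
    }
    for (int nf : newFaces)
      if (!faces[nf].outside.empty()) stack.push_back(nf);
  }

  int nf = 0;
  for (size_t k = 0; k < faces.size(); ++k) if (faces[k].alive) nf++;
  IntegerMatrix tri(nf, 3);
  int r = 0;
  for (size_t k = 0; k < faces.size(); ++k)
    if (faces[k].alive) {
      tri(r, 0) = faces[k].a + 1;
      tri(r, 1) = faces[k].b + 1;
      tri(r, 2) = faces[k].c + 1;
      r++;
    }
  return List::create(_["triangles"] = tri);
}
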