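#include <Rcpp.h>
#include <set>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Brute-force Delaunay edge enumeration. At the scale this package targets
// (tens to a few hundred labeled cell centers per volume) exhaustive
// empty-circumsphere testing is fast, deterministic and free of the
// numerical-robustness machinery an incremental triangulator needs.

static inline double dist2_3(const double* p, const double* q) {
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// Circumsphere of 4 points: solve 2 (p_j - p_0) . c = |p_j|^2 - |p_0|^2.
// Returns false when the tetrahedron is (near-)degenerate.
static bool circumsphere(const double* a, const double* b, const double* c,
                         const double* d, double degen_tol,
                         double* center, double* r2) {
  double M[3][3], rhs[3];
  const double* pts[3] = { b, c, d };
  double a2 = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
  for (int i = 0; i < 3; ++i) {
    const double* p = pts[i];
    for (int j = 0; j < 3; ++j) M[i][j] = 2.0 * (p[j] - a[j]);
    rhs[i] = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - a2;
  }
  double det =
      M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
      M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
      M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) < degen_tol) return false;
  double inv = 1.0 / det;
  center[0] = inv * (rhs[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
                     M[0][1] * (rhs[1] * M[2][2] - M[1][2] * rhs[2]) +
                     M[0][2] * (rhs[1] * M[2][1] - M[1][1] * rhs[2]));
  center[1] = inv * (M[0][0] * (rhs[1] * M[2][2] - M[1][2] * rhs[2]) -
                     rhs[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
                     M[0][2] * (M[1][0] * rhs[2] - rhs[1] * M[2][0]));
  center[2] = inv * (M[0][0] * (M[1][1] * rhs[2] - rhs[1] * M[2][1]) -
                     M[0][1] * (M[1][0] * rhs[2] - rhs[1] * M[2][0]) +
                     rhs[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]));
  *r2 = dist2_3(center, a);
  return true;
}

// Edge union of the 3D Delaunay triangulation of `pts` (n x 3, physical
// units). A tetrahedron belongs to the triangulation iff its circumsphere
// contains no other point strictly inside (relative tolerance keeps
// cospherical configurations on the boundary, so ties contribute the
// union of all valid triangulations).
// [[Rcpp::export(name = ".delaunayEdges3D")]]
IntegerMatrix delaunay_edges_3d(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> P(3 * n);
  double spread = 0.0;
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pts(i, 0);
    P[3 * i + 1] = pts(i, 1);
    P[3 * i + 2] = pts(i, 2);
  }
  for (int k = 0; k < 3; ++k) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = P[3 * i + k];
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    spread = std::max(spread, mx - mn);
  }
  if (spread <= 0.0) spread = 1.0;
  // det scales as length^3 (rows are 2*differences): treat smaller as flat
  double degen_tol = 1e-10 * spread * spread * spread;
  std::set<std::pair<int, int> > edges;
  double c[3], r2;
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j)
      for (int k = j + 1; k < n - 1; ++k)
        for (int l = k + 1; l < n; ++l) {
          if (!circumsphere(&P[3 * i], &P[3 * j], &P[3 * k], &P[3 * l],
                            degen_tol, c, &r2))
            continue;
          double lim = r2 * (1.0 - 1e-9);
          bool empty = true;
          for (int m = 0; m < n; ++m) {
            if (m == i || m == j || m == k || m == l) continue;
            if (dist2_3(c, &P[3 * m]) < lim) { empty = false; break; }
          }
          if (!empty) continue;
          int v[4] = { i, j, k, l };
          for (int s = 0; s < 4; ++s)
            for (int t = s + 1; t < 4; ++t)
              edges.insert(std::make_pair(v[s], v[t]));
        }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;  // 1-based row indices for R
    out(r, 1) = it->second + 1;
  }
  return out;
}

// 2D analogue (empty circumcircle over all triples), used as the fallback
// for exactly coplanar point sets projected into their best-fit plane.
// [[Rcpp::export(name = ".delaunayEdges2D")]]
IntegerMatrix delaunay_edges_2d(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> X(n), Y(n);
  double spread = 0.0;
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); }
  {
    double mnx = R_PosInf, mxx = R_NegInf, mny = R_PosInf, mxy = R_NegInf;
    for (int i = 0; i < n; ++i) {
      mnx = std::min(mnx, X[i]); mxx = std::max(mxx, X[i]);
      mny = std::min(mny, Y[i]); mxy = std::max(mxy, Y[i]);
    }
    spread = std::max(mxx - mnx, mxy - mny);
  }
  if (spread <= 0.0) spread = 1.0;
  double degen_tol = 1e-10 * spread * spread;
  std::set<std::pair<int, int> > edges;
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j)
      for (int k = j + 1; k < n; ++k) {
        double ax = X[i], ay = Y[i], bx = X[j], by = Y[j], cx = X[k], cy = Y[k];
        double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
        if (std::fabs(d) < degen_tol) continue;
        double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               c2 = cx * cx + cy * cy;
        double ux = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
        double uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
        double r2 = (ux - ax) * (ux - ax) + (uy - ay) * (uy - ay);
        double lim = r2 * (1.0 - 1e-9);
        bool empty = true;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double d2 = (ux - X[m]) * (ux - X[m]) + (uy - Y[m]) * (uy - Y[m]);
          if (d2 < lim) { empty = false; break; }
        }
        if (!empty) continue;
        int v[3] = { i, j, k };
        for (int s = 0; s < 3; ++s)
          for (int t = s + 1; t < 3; ++t)
            edges.insert(std::make_pair(v[s], v[t]));
      }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;
    out(r, 1) = it->second + 1;
  }
  return out;
}
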