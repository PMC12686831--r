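#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Ray-triangle and point-triangle kernels for triangulated CT surfaces.
// Vertices are an n x 3 matrix (mm), faces an m x 3 matrix of 1-based
// vertex indices. Exhaustive iteration over triangles: mesh sizes in this
// package (a few thousand faces) make an acceleration structure
// unnecessary, and the simple loop is the easiest to validate against an
// independent R-level oracle.

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Moller-Trumbore, nearest hit with t > tmin (self-intersection guard).
// Flatten triangle data (v0, e1 = v1 - v0, e2 = v2 - v0) once per call so
// the inner loop runs on contiguous doubles.
static std::vector<double> flatten_tris(const NumericMatrix& V,
                                        const IntegerMatrix& F) {
  const int nf = F.nrow();
  std::vector<double> T(9 * nf);
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double* t = &T[9 * f];
    for (int k = 0; k < 3; ++k) {
      t[k] = V(i0, k);
      t[3 + k] = V(i1, k) - V(i0, k);
      t[6 + k] = V(i2, k) - V(i0, k);
    }
  }
  return T;
}

// [[Rcpp::export]]
List cpp_raycast(NumericMatrix V, IntegerMatrix F, NumericMatrix origins,
                 NumericMatrix dirs, double tmin) {
  const int nf = F.nrow(), nr = origins.nrow();
  NumericVector tbest(nr, NA_REAL);
  IntegerVector fbest(nr, NA_INTEGER);
  NumericMatrix pts(nr, 3);
  std::fill(pts.begin(), pts.end(), NA_REAL);
  const std::vector<double> T = flatten_tris(V, F);

  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    double best = std::numeric_limits<double>::infinity();
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      const double* tri = &T[9 * f];
      const double* v0 = tri;
      const double* e1 = tri + 3;
      const double* e2 = tri + 6;
      double pvec[3];
      cross3(d, e2, pvec);
      double det = dot3(e1, pvec);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double svec[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
      double u = dot3(svec, pvec) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qvec[3];
      cross3(svec, e1, qvec);
      double v = dot3(d, qvec) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = dot3(e2, qvec) * inv;
      if (t > tmin && t < best) {
        best = t;
        bestf = f;
      }
    }
    if (bestf >= 0) {
      tbest[r] = best;
      fbest[r] = bestf + 1;
      for (int k = 0; k < 3; ++k) pts(r, k) = o[k] + best * d[k];
    }
  }
  return List::create(_["t"] = tbest, _["face"] = fbest, _["point"] = pts);
}

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static inline double closest_on_tri(const double p[3], const double a[3],
                                    const double b[3], const double c[3],
                                    double out[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  double cx[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    cx[0] = a[0]; cx[1] = a[1]; cx[2] = a[2];
  } else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) {
      cx[0] = b[0]; cx[1] = b[1]; cx[2] = b[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) cx[k] = a[k] + v * ab[k];
      } else {
        double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
        double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
        if (d6 >= 0.0 && d5 <= d6) {
          cx[0] = c[0]; cx[1] = c[1]; cx[2] = c[2];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) cx[k] = a[k] + w * ac[k];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) cx[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k) cx[k] = a[k] + ab[k] * v + ac[k] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - cx[0], dy = p[1] - cx[1], dz = p[2] - cx[2];
  out[0] = cx[0]; out[1] = cx[1]; out[2] = cx[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  const int nf = F.nrow(), np = P.nrow();
  NumericVector dist(np);
  NumericMatrix pts(np, 3);
  IntegerVector face(np);
  std::vector<double> T(9 * nf);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      T[9 * f + k] = V(F(f, 0) - 1, k);
      T[9 * f + 3 + k] = V(F(f, 1) - 1, k);
      T[9 * f + 6 + k] = V(F(f, 2) - 1, k);
    }
  for (int r = 0; r < np; ++r) {
    double p[3] = {P(r, 0), P(r, 1), P(r, 2)};
    double best = std::numeric_limits<double>::infinity();
    double bestpt[3] = {0, 0, 0};
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      const double* a = &T[9 * f];
      const double* b = a + 3;
      const double* c = a + 6;
      double q[3];
      double d = closest_on_tri(p, a, b, c, q);
      if (d < best) {
        best = d;
        bestf = f;
        bestpt[0] = q[0]; bestpt[1] = q[1]; bestpt[2] = q[2];
      }
    }
    dist[r] = best;
    face[r] = bestf + 1;
    for (int k = 0; k < 3; ++k) pts(r, k) = bestpt[k];
  }
  return List::create(_["distance"] = dist, _["point"] = pts,
                      _["face"] = face);
}
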