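// Geometry kernels shared by the deviation and planning code:
//  - closest point on a triangle mesh (exact, with a centroid-bound prune)
//  - ray / mesh intersections (Moller-Trumbore)

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline void closest_point_triangle(const double *p, const double *a,
                                          const double *b, const double *c,
                                          double *out) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix query, NumericMatrix verts,
                        IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  NumericMatrix points(nq, 3);
  NumericVector dists(nq);
  IntegerVector fidx(nq);

  // triangle corner caches + centroid/radius for pruning
  std::vector<double> A(3 * nf), B(3 * nf), C(3 * nf), CEN(3 * nf), RAD(nf);
  for (int f = 0; f < nf; ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      A[3*f+k] = verts(ia, k);
      B[3*f+k] = verts(ib, k);
      C[3*f+k] = verts(ic, k);
      CEN[3*f+k] = (A[3*f+k] + B[3*f+k] + C[3*f+k]) / 3.0;
    }
    for (int k = 0; k < 3; ++k) {
      double da = A[3*f+k] - CEN[3*f+k], db = B[3*f+k] - CEN[3*f+k],
             dc = C[3*f+k] - CEN[3*f+k];
      r2 += std::max(da*da, std::max(db*db, dc*dc));
    }
    RAD[f] = std::sqrt(r2);
  }

  std::vector<double> cdist(nf);
  for (int q = 0; q < nq; ++q) {
    double p[3] = { query(q, 0), query(q, 1), query(q, 2) };
    // pass 1: centroid distances give an upper bound on the true minimum
    double ub = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - CEN[3*f], dy = p[1] - CEN[3*f+1], dz = p[2] - CEN[3*f+2];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      cdist[f] = d;
      if (d + RAD[f] < ub) ub = d + RAD[f];
    }
    // pass 2: exact tests on triangles whose lower bound beats ub
    double best = std::numeric_limits<double>::infinity();
    int bestf = 0;
    double bestp[3] = {0, 0, 0};
    for (int f = 0; f < nf; ++f) {
      if (cdist[f] - RAD[f] > best || cdist[f] - RAD[f] > ub) continue;
      double cp[3];
      closest_point_triangle(p, &A[3*f], &B[3*f], &C[3*f], cp);
      double dx = p[0]-cp[0], dy = p[1]-cp[1], dz = p[2]-cp[2];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < best) {
        best = d; bestf = f;
        bestp[0] = cp[0]; bestp[1] = cp[1]; bestp[2] = cp[2];
      }
    }
    dists[q] = best;
    fidx[q] = bestf + 1;
    points(q, 0) = bestp[0]; points(q, 1) = bestp[1]; points(q, 2) = bestp[2];
  }
  return List::create(_["points"] = points, _["dist"] = dists,
                      _["face"] = fidx);
}

// [[Rcpp::export(name = ".cpp_ray_mesh")]]
NumericVector cpp_ray_mesh(NumericVector orig, NumericVector dir,
                           NumericMatrix verts, IntegerMatrix faces) {
  // all positive ray parameters t where orig + t*dir crosses a face
  const int nf = faces.nrow();
  const double eps = 1e-9;
  std::vector<double> hits;
  for (int f = 0; f < nf; ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    double e1[3], e2[3], pv[3], tv[3], qv[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = verts(ib, k) - verts(ia, k);
      e2[k] = verts(ic, k) - verts(ia, k);
    }
    pv[0] = dir[1]*e2[2] - dir[2]*e2[1];
    pv[1] = dir[2]*e2[0] - dir[0]*e2[2];
    pv[2] = dir[0]*e2[1] - dir[1]*e2[0];
    double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    for (int k = 0; k < 3; ++k) tv[k] = orig[k] - verts(ia, k);
    double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) continue;
    qv[0] = tv[1]*e1[2] - tv[2]*e1[1];
    qv[1] = tv[2]*e1[0] - tv[0]*e1[2];
    qv[2] = tv[0]*e1[1] - tv[1]*e1[0];
    double v = (dir[0]*qv[0] + dir[1]*qv[1] + dir[2]*qv[2]) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) continue;
    double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
    if (t > eps) hits.push_back(t);
  }
  return wrap(hits);
}
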