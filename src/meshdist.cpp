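#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection)
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// For each query point, the closest point on any triangle of the mesh
// (brute force with per-triangle bounding-sphere pruning).
// [[Rcpp::export(name = ".closest_point_mesh")]]
List closest_point_mesh(NumericMatrix query, NumericMatrix verts,
                        IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  if (nf == 0) stop("closest_point_mesh: mesh has no faces");
  // triangle centroids and bounding radii for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    const int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    double gx = (verts(i0,0) + verts(i1,0) + verts(i2,0)) / 3.0;
    double gy = (verts(i0,1) + verts(i1,1) + verts(i2,1)) / 3.0;
    double gz = (verts(i0,2) + verts(i1,2) + verts(i2,2)) / 3.0;
    cx[f] = gx; cy[f] = gy; cz[f] = gz;
    double r2 = 0;
    const int ids[3] = {i0, i1, i2};
    for (int k = 0; k < 3; ++k) {
      double dx = verts(ids[k],0) - gx, dy = verts(ids[k],1) - gy,
             dz = verts(ids[k],2) - gz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  NumericVector dist(nq);
  NumericMatrix cpts(nq, 3);
  IntegerVector fidx(nq);
  double tri_a[3], tri_b[3], tri_c[3], p[3], best_pt[3], out[3];
  for (int q = 0; q < nq; ++q) {
    p[0] = query(q,0); p[1] = query(q,1); p[2] = query(q,2);
    double best = std::numeric_limits<double>::infinity();
    int best_f = -1;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-cx[f], dy = p[1]-cy[f], dz = p[2]-cz[f];
      double dcen = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (dcen - rad[f] >= std::sqrt(best)) continue;
      const int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1,
                i2 = faces(f, 2) - 1;
      for (int i = 0; i < 3; ++i) {
        tri_a[i] = verts(i0, i); tri_b[i] = verts(i1, i); tri_c[i] = verts(i2, i);
      }
      closest_on_tri(p, tri_a, tri_b, tri_c, out);
      double ddx = p[0]-out[0], ddy = p[1]-out[1], ddz = p[2]-out[2];
      double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
      if (d2 < best) {
        best = d2; best_f = f;
        best_pt[0] = out[0]; best_pt[1] = out[1]; best_pt[2] = out[2];
      }
    }
    dist[q] = std::sqrt(best);
    cpts(q,0) = best_pt[0]; cpts(q,1) = best_pt[1]; cpts(q,2) = best_pt[2];
    fidx[q] = best_f + 1;
  }
  return List::create(_["dist"] = dist, _["points"] = cpts,
                      _["face"] = fidx);
}
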