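#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <set>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Iterative quadric edge-collapse decimation (Garland-Heckbert error
// quadrics) with optional volume preservation: the collapse position is
// the quadric-optimal point projected onto the plane of zero local
// volume change (the swept volume is affine in the new position), and
// the collapse cost additionally penalises residual local volume change
// (alpha) and triangle-normal deviation (beta). Collapses that would
// flip a surviving triangle's normal or break the manifold link
// condition are rejected. Deterministic tie-breaking by (cost, lower
// vertex index, higher vertex index).

struct Quadric {
  // symmetric 4x4 stored as upper triangle: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  double q[10];
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0; }
  void add_plane(double nx, double ny, double nz, double d, double w) {
    double v[4] = {nx, ny, nz, d};
    int k = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j) q[k++] += w * v[i] * v[j];
  }
  void add(const Quadric &o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    double v[4] = {x, y, z, 1.0};
    double m[4][4] = {
      {q[0], q[1], q[2], q[3]},
      {q[1], q[4], q[5], q[6]},
      {q[2], q[5], q[7], q[8]},
      {q[3], q[6], q[8], q[9]}};
    double s = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) s += v[i] * m[i][j] * v[j];
    return s;
  }
  // minimiser of the quadratic form; false if near-singular
  bool optimum(double *out) const {
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
    double scale = std::abs(A[0][0]) + std::abs(A[1][1]) + std::abs(A[2][2]);
    if (std::abs(det) < 1e-10 * scale * scale * scale + 1e-300) return false;
    double inv[3][3];
    inv[0][0] =  (A[1][1]*A[2][2]-A[1][2]*A[2][1]) / det;
    inv[0][1] = -(A[0][1]*A[2][2]-A[0][2]*A[2][1]) / det;
    inv[0][2] =  (A[0][1]*A[1][2]-A[0][2]*A[1][1]) / det;
    inv[1][0] = -(A[1][0]*A[2][2]-A[1][2]*A[2][0]) / det;
    inv[1][1] =  (A[0][0]*A[2][2]-A[0][2]*A[2][0]) / det;
    inv[1][2] = -(A[0][0]*A[1][2]-A[0][2]*A[1][0]) / det;
    inv[2][0] =  (A[1][0]*A[2][1]-A[1][1]*A[2][0]) / det;
    inv[2][1] = -(A[0][0]*A[2][1]-A[0][1]*A[2][0]) / det;
    inv[2][2] =  (A[0][0]*A[1][1]-A[0][1]*A[1][0]) / det;
    for (int i = 0; i < 3; ++i)
      out[i] = inv[i][0]*b[0] + inv[i][1]*b[1] + inv[i][2]*b[2];
    return true;
  }
};

struct Cand {
  double cost;
  int a, b;          // a < b
  uint64_t va, vb;   // vertex versions at push time
  double px, py, pz;
};
struct CandCmp {
  bool operator()(const Cand &x, const Cand &y) const {
    if (x.cost != y.cost) return x.cost > y.cost;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

class Decimator {
public:
  std::vector<double> vx, vy, vz;
  std::vector<std::array<int,3>> F;
  std::vector<bool> face_alive, vert_alive;
  std::vector<std::set<int>> vfaces;   // incident faces per vertex
  std::vector<Quadric> Q;
  std::vector<uint64_t> version;
  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;
  bool preserve_volume;
  double alpha, beta;
  int n_faces_alive;

  void face_normal(int f, double *n, double *area) const {
    const auto &t = F[f];
    double ux = vx[t[1]]-vx[t[0]], uy = vy[t[1]]-vy[t[0]], uz = vz[t[1]]-vz[t[0]];
    double wx = vx[t[2]]-vx[t[0]], wy = vy[t[2]]-vy[t[0]], wz = vz[t[2]]-vz[t[0]];
    n[0] = uy*wz - uz*wy; n[1] = uz*wx - ux*wz; n[2] = ux*wy - uy*wx;
    double l = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    *area = 0.5 * l;
    if (l > 0) { n[0] /= l; n[1] /= l; n[2] /= l; }
  }

  void init_quadrics() {
    Q.assign(vx.size(), Quadric());
    double n[3], area;
    for (size_t f = 0; f < F.size(); ++f) {
      face_normal((int)f, n, &area);
      if (area <= 0) continue;
      double d = -(n[0]*vx[F[f][0]] + n[1]*vy[F[f][0]] + n[2]*vz[F[f][0]]);
      for (int k = 0; k < 3; ++k) {
        Quadric p; p.add_plane(n[0], n[1], n[2], d, area / 3.0);
        Q[F[f][k]].add(p);
      }
    }
  }

  // evaluate a candidate collapse (a,b); returns false if invalid
  bool evaluate(int a, int b, Cand *out) {
    if (!vert_alive[a] || !vert_alive[b]) return false;
    // faces shared by a and b, and the "link" third vertices
    std::vector<int> shared;
    std::set<int> link_third;
    for (int f : vfaces[a])
      if (vfaces[b].count(f)) {
        shared.push_back(f);
        for (int k = 0; k < 3; ++k)
          if (F[f][k] != a && F[f][k] != b) link_third.insert(F[f][k]);
      }
    if (shared.empty()) return false;
    // link condition: common vertex neighbours of a and b must be
    // exactly the third vertices of the shared faces
    std::set<int> na, common;
    for (int f : vfaces[a]) for (int k = 0; k < 3; ++k)
      if (F[f][k] != a) na.insert(F[f][k]);
    for (int f : vfaces[b]) for (int k = 0; k < 3; ++k)
      if (F[f][k] != b && F[f][k] != a && na.count(F[f][k]))
        common.insert(F[f][k]);
    if (common != link_third) return false;

    Quadric qq = Q[a]; qq.add(Q[b]);
    double p[3];
    if (!qq.optimum(p)) {
      // fall back to best of (midpoint, a, b)
      double cands[3][3] = {
        {(vx[a]+vx[b])/2, (vy[a]+vy[b])/2, (vz[a]+vz[b])/2},
        {vx[a], vy[a], vz[a]}, {vx[b], vy[b], vz[b]}};
      double best = std::numeric_limits<double>::infinity();
      for (int i = 0; i < 3; ++i) {
        double e = qq.eval(cands[i][0], cands[i][1], cands[i][2]);
        if (e < best) { best = e; p[0]=cands[i][0]; p[1]=cands[i][1]; p[2]=cands[i][2]; }
      }
    }
    // local volume change is affine in p: dV(p) = g.p + c
    double g[3] = {0, 0, 0}, c = 0;
    for (int v01 = 0; v01 < 2; ++v01) {
      int v = v01 ? b : a;
      for (int f : vfaces[v]) {
        bool is_shared = false;
        for (int s : shared) if (s == f) { is_shared = true; break; }
        const auto &t = F[f];
        double before = (vx[t[0]]*(vy[t[1]]*vz[t[2]] - vz[t[1]]*vy[t[2]])
                       - vy[t[0]]*(vx[t[1]]*vz[t[2]] - vz[t[1]]*vx[t[2]])
                       + vz[t[0]]*(vx[t[1]]*vy[t[2]] - vy[t[1]]*vx[t[2]])) / 6.0;
        c -= before;
        if (is_shared) continue;   // degenerates after collapse: after-volume 0
        // after-volume is p . (cross of the two fixed vertices) / 6,
        // with sign depending on the slot the moving vertex occupies
        int slot = (t[0] == v) ? 0 : (t[1] == v) ? 1 : 2;
        int o1 = t[(slot + 1) % 3], o2 = t[(slot + 2) % 3];
        g[0] += (vy[o1]*vz[o2] - vz[o1]*vy[o2]) / 6.0;
        g[1] += (vz[o1]*vx[o2] - vx[o1]*vz[o2]) / 6.0;
        g[2] += (vx[o1]*vy[o2] - vy[o1]*vx[o2]) / 6.0;
      }
    }
    // shared faces were visited from both a and b: un-count one copy
    for (int s : shared) {
      const auto &t = F[s];
      double before = (vx[t[0]]*(vy[t[1]]*vz[t[2]] - vz[t[1]]*vy[t[2]])
                     - vy[t[0]]*(vx[t[1]]*vz[t[2]] - vz[t[1]]*vx[t[2]])
                     + vz[t[0]]*(vx[t[1]]*vy[t[2]] - vy[t[1]]*vx[t[2]])) / 6.0;
      c += before;
    }
    if (preserve_volume) {
      double g2 = g[0]*g[0] + g[1]*g[1] + g[2]*g[2];
      if (g2 > 1e-300) {
        double lam = (g[0]*p[0] + g[1]*p[1] + g[2]*p[2] + c) / g2;
        p[0] -= lam * g[0]; p[1] -= lam * g[1]; p[2] -= lam * g[2];
      }
    }
    double dV = g[0]*p[0] + g[1]*p[1] + g[2]*p[2] + c;
    // normal deviation / flip test on surviving faces
    double min_cos = 1.0;
    for (int v01 = 0; v01 < 2; ++v01) {
      int v = v01 ? b : a;
      double ox = vx[v], oy = vy[v], oz = vz[v];
      for (int f : vfaces[v]) {
        bool is_shared = false;
        for (int s : shared) if (s == f) { is_shared = true; break; }
        if (is_shared) continue;
        double n0[3], n1[3], area;
        face_normal(f, n0, &area);
        vx[v] = p[0]; vy[v] = p[1]; vz[v] = p[2];
        face_normal(f, n1, &area);
        vx[v] = ox; vy[v] = oy; vz[v] = oz;
        double cosd = n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2];
        if (cosd < min_cos) min_cos = cosd;
      }
    }
    if (min_cos < 0) return false;   // would flip a triangle
    out->cost = qq.eval(p[0], p[1], p[2]) + alpha * std::abs(dV)
              + beta * (1.0 - min_cos);
    out->a = a; out->b = b; out->va = version[a]; out->vb = version[b];
    out->px = p[0]; out->py = p[1]; out->pz = p[2];
    return true;
  }

  void push_edges_of(int v) {
    std::set<int> nb;
    for (int f : vfaces[v]) for (int k = 0; k < 3; ++k)
      if (F[f][k] != v) nb.insert(F[f][k]);
    Cand c;
    for (int u : nb) {
      int a = std::min(u, v), b = std::max(u, v);
      if (evaluate(a, b, &c)) pq.push(c);
    }
  }

  // One pass over the queue; returns number of collapses performed.
  // Popped candidates are re-evaluated before execution, so stale
  // priorities cost only ordering accuracy, never correctness.
  long drain(int target_faces) {
    long done = 0;
    while (n_faces_alive > target_faces && !pq.empty()) {
      Cand c = pq.top(); pq.pop();
      if (!vert_alive[c.a] || !vert_alive[c.b]) continue;
      if (version[c.a] != c.va || version[c.b] != c.vb) continue;
      Cand fresh;
      if (!evaluate(c.a, c.b, &fresh)) continue;
      // perform collapse: b merges into a at the evaluated position
      int a = c.a, b = c.b;
      std::vector<int> shared;
      for (int f : vfaces[a]) if (vfaces[b].count(f)) shared.push_back(f);
      if ((int)shared.size() > n_faces_alive - target_faces)
        continue;   // would overshoot the target count
      vx[a] = fresh.px; vy[a] = fresh.py; vz[a] = fresh.pz;
      for (int f : shared) {
        if (face_alive[f]) { face_alive[f] = false; --n_faces_alive; }
        for (int k = 0; k < 3; ++k) vfaces[F[f][k]].erase(f);
      }
      std::vector<int> bf(vfaces[b].begin(), vfaces[b].end());
      for (int f : bf) {
        for (int k = 0; k < 3; ++k) if (F[f][k] == b) F[f][k] = a;
        vfaces[b].erase(f);
        vfaces[a].insert(f);
      }
      vert_alive[b] = false;
      Q[a].add(Q[b]);
      ++version[a];
      push_edges_of(a);
      ++done;
    }
    return done;
  }

  void run(int target_faces) {
    init_quadrics();
    version.assign(vx.size(), 0);
    for (size_t v = 0; v < vx.size(); ++v)
      if (vert_alive[v]) push_edges_of((int)v);
    while (n_faces_alive > target_faces) {
      long done = drain(target_faces);
      if (n_faces_alive <= target_faces) break;
      // queue exhausted: refresh candidates for surviving edges and
      // retry; stop when a full refresh makes no progress
      for (size_t v = 0; v < vx.size(); ++v)
        if (vert_alive[v]) push_edges_of((int)v);
      if (drain(target_faces) == 0) break;
    }
  }
};

// [[Rcpp::export(name = ".decimate_qem")]]
List decimate_qem(NumericMatrix verts, IntegerMatrix faces,
                  int target_faces, bool preserve_volume,
                  double alpha, double beta) {
  Decimator D;
  const int nv = verts.nrow(), nf = faces.nrow();
  D.vx.resize(nv); D.vy.resize(nv); D.vz.resize(nv);
  for (int i = 0; i < nv; ++i) {
    D.vx[i] = verts(i,0); D.vy[i] = verts(i,1); D.vz[i] = verts(i,2);
  }
  D.F.resize(nf);
  D.vfaces.assign(nv, std::set<int>());
  for (int f = 0; f < nf; ++f) {
    D.F[f] = {faces(f,0)-1, faces(f,1)-1, faces(f,2)-1};
    for (int k = 0; k < 3; ++k) D.vfaces[D.F[f][k]].insert(f);
  }
  D.face_alive.assign(nf, true);
  D.vert_alive.assign(nv, true);
  D.n_faces_alive = nf;
  D.preserve_volume = preserve_volume;
  D.alpha = alpha; D.beta = beta;
  D.run(target_faces);

  // compact the surviving mesh
  std::vector<int> vmap(nv, -1);
  std::vector<int> keep;
  for (int f = 0; f < nf; ++f)
    if (D.face_alive[f])
      for (int k = 0; k < 3; ++k)
        if (vmap[D.F[f][k]] < 0) {
          vmap[D.F[f][k]] = (int)keep.size();
          keep.push_back(D.F[f][k]);
        }
  NumericMatrix out_v((int)keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    out_v(i,0) = D.vx[keep[i]]; out_v(i,1) = D.vy[keep[i]];
    out_v(i,2) = D.vz[keep[i]];
  }
  IntegerMatrix out_f(D.n_faces_alive, 3);
  int r = 0;
  for (int f = 0; f < nf; ++f)
    if (D.face_alive[f]) {
      for (int k = 0; k < 3; ++k) out_f(r, k) = vmap[D.F[f][k]] + 1;
      ++r;
    }
  return List::create(_["vertices"] = out_v, _["faces"] = out_f);
}
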