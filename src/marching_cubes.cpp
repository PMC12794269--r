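#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Table-driven isosurface triangulation on a structured grid. The
// per-configuration triangle table is generated on the R side (see
// mc_case_table()); this routine does the per-cell work: corner
// classification, edge-crossing vertex placement by linear
// interpolation, and global vertex welding keyed on lattice edges so
// shared vertices are emitted exactly once.
//
// A lattice point (ix,iy,iz) has linear index ix + nx*(iy + ny*iz);
// the lattice edge starting there along axis a has key 3*linear + a.

// [[Rcpp::export(name = ".mc_triangulate")]]
List mc_triangulate(NumericVector data, IntegerVector dims,
                    NumericVector spacing, NumericVector origin,
                    double iso, IntegerMatrix tri_table,
                    IntegerMatrix edge_corners) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // corner id c -> lattice offset bits
  int coff[8][3];
  for (int c = 0; c < 8; ++c) {
    coff[c][0] = c & 1; coff[c][1] = (c >> 1) & 1; coff[c][2] = (c >> 2) & 1;
  }

  std::unordered_map<int64_t, int> vert_of_edge;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double corner_val[8];
  for (int kz = 0; kz < nz - 1; ++kz)
    for (int ky = 0; ky < ny - 1; ++ky)
      for (int kx = 0; kx < nx - 1; ++kx) {
        int mask = 0;
        for (int c = 0; c < 8; ++c) {
          const int ix = kx + coff[c][0], iy = ky + coff[c][1],
                    iz = kz + coff[c][2];
          const double v = data[ix + (int64_t)nx * (iy + (int64_t)ny * iz)];
          corner_val[c] = v;
          if (v > iso) mask |= (1 << c);
        }
        if (mask == 0 || mask == 255) continue;
        for (int t = 0; t < tri_table.ncol(); t += 3) {
          if (tri_table(mask, t) < 0) break;
          int ids[3];
          for (int k = 0; k < 3; ++k) {
            const int e = tri_table(mask, t + k);
            const int c0 = edge_corners(e, 0), c1 = edge_corners(e, 1);
            // axis along which the edge runs, and its lower lattice point
            int axis = 0;
            for (int a = 0; a < 3; ++a)
              if (coff[c0][a] != coff[c1][a]) axis = a;
            const int lx = kx + std::min(coff[c0][0], coff[c1][0]);
            const int ly = ky + std::min(coff[c0][1], coff[c1][1]);
            const int lz = kz + std::min(coff[c0][2], coff[c1][2]);
            const int64_t key =
              3 * ((int64_t)lx + (int64_t)nx * ((int64_t)ly + (int64_t)ny * lz)) + axis;
            auto it = vert_of_edge.find(key);
            if (it != vert_of_edge.end()) { ids[k] = it->second; continue; }
            // interpolate from the lower lattice point toward the upper
            const int clow = (coff[c0][axis] < coff[c1][axis]) ? c0 : c1;
            const int chigh = (clow == c0) ? c1 : c0;
            const double v0 = corner_val[clow], v1 = corner_val[chigh];
            double tt = (v1 != v0) ? (iso - v0) / (v1 - v0) : 0.5;
            if (tt < 0) tt = 0; if (tt > 1) tt = 1;
            double px = ox + (lx + (axis == 0 ? tt : 0.0)) * sx;
            double py = oy + (ly + (axis == 1 ? tt : 0.0)) * sy;
            double pz = oz + (lz + (axis == 2 ? tt : 0.0)) * sz;
            const int id = (int)vx.size();
            vx.push_back(px); vy.push_back(py); vz.push_back(pz);
            vert_of_edge.emplace(key, id);
            ids[k] = id;
          }
          // drop degenerate triangles from iso hitting a lattice value
          if (ids[0] == ids[1] || ids[1] == ids[2] || ids[0] == ids[2])
            continue;
          tri.push_back(ids[0]); tri.push_back(ids[1]); tri.push_back(ids[2]);
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  const int nf = (int)tri.size() / 3;
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = tri[3 * i] + 1;
    faces(i, 1) = tri[3 * i + 1] + 1;
    faces(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
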