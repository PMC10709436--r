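#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction on the voxel grid. Each cell is decomposed into the
// six Kuhn tetrahedra around the (0,0,0)-(1,1,1) diagonal; the decomposition
// tiles the grid consistently, so interpolated edge vertices are shared
// between neighbouring cells and the welded surface is watertight, avoiding
// the ambiguous-case cracks of the classic cube-table formulation.
// Triangles are wound so normals point away from the supra-level region.

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export]]
List cpp_isosurface(NumericVector vol, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);
  auto lin = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  // vertex on the grid edge between corners a (global lin ia) and b
  auto edge_point = [&](int pa[3], int pb[3], double fa, double fb) -> int {
    uint64_t ia = (uint64_t)lin(pa[0], pa[1], pa[2]);
    uint64_t ib = (uint64_t)lin(pb[0], pb[1], pb[2]);
    uint64_t key = (ia < ib) ? ia * (uint64_t)4294967296ULL + ib
                             : ib * (uint64_t)4294967296ULL + ia;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  };

  auto emit = [&](int a, int b, int c, const double above_c[3],
                  const double below_c[3]) {
    // orient: normal should point from the supra-level side to the sub-level
    double e1x = vx[b] - vx[a], e1y = vy[b] - vy[a], e1z = vz[b] - vz[a];
    double e2x = vx[c] - vx[a], e2y = vy[c] - vy[a], e2z = vz[c] - vz[a];
    double nxv = e1y * e2z - e1z * e2y;
    double nyv = e1z * e2x - e1x * e2z;
    double nzv = e1x * e2y - e1y * e2x;
    double dx = below_c[0] - above_c[0], dy = below_c[1] - above_c[1],
           dz = below_c[2] - above_c[2];
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  int P[8][3];
  double F[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          P[c][0] = i + CORNER[c][0];
          P[c][1] = j + CORNER[c][1];
          P[c][2] = k + CORNER[c][2];
          F[c] = v[lin(P[c][0], P[c][1], P[c][2])];
          (F[c] > level ? any_above : any_below) = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          int a[3], b[3], na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            int vi = TETS[t][c];
            if (F[vi] > level) a[na++] = vi; else b[nb++] = vi;
          }
          if (na == 0 || na == 4) continue;
          double ac[3] = {0, 0, 0}, bc[3] = {0, 0, 0};
          for (int c = 0; c < na; ++c)
            for (int d = 0; d < 3; ++d) ac[d] += P[a[c]][d] / (double)na;
          for (int c = 0; c < nb; ++c)
            for (int d = 0; d < 3; ++d) bc[d] += P[b[c]][d] / (double)nb;
          if (na == 1) {
            int e0 = edge_point(P[a[0]], P[b[0]], F[a[0]], F[b[0]]);
            int e1 = edge_point(P[a[0]], P[b[1]], F[a[0]], F[b[1]]);
            int e2 = edge_point(P[a[0]], P[b[2]], F[a[0]], F[b[2]]);
            emit(e0, e1, e2, ac, bc);
          } else if (na == 3) {
            int e0 = edge_point(P[a[0]], P[b[0]], F[a[0]], F[b[0]]);
            int e1 = edge_point(P[a[1]], P[b[0]], F[a[1]], F[b[0]]);
            int e2 = edge_point(P[a[2]], P[b[0]], F[a[2]], F[b[0]]);
            emit(e0, e1, e2, ac, bc);
          } else { // 2-2: quad split into two triangles
            int q0 = edge_point(P[a[0]], P[b[0]], F[a[0]], F[b[0]]);
            int q1 = edge_point(P[a[1]], P[b[0]], F[a[1]], F[b[0]]);
            int q2 = edge_point(P[a[1]], P[b[1]], F[a[1]], F[b[1]]);
            int q3 = edge_point(P[a[0]], P[b[1]], F[a[0]], F[b[1]]);
            emit(q0, q1, q2, ac, bc);
            emit(q0, q2, q3, ac, bc);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = tri[3 * i] + 1;
    faces(i, 1) = tri[3 * i + 1] + 1;
    faces(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
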