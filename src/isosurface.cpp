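// Marching-tetrahedra isosurface extraction on a regular grid.
// Each cube is split into 5 tetrahedra with a parity-alternating pattern so
// that face diagonals match between neighboring cubes; vertices are welded
// on grid edges, which makes internally generated meshes closed and manifold.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based vertex ids, 3 per triangle
  std::unordered_map<uint64_t, int> edgeVert;

  int vertex_on_edge(int g1, int g2, const double *p1, const double *p2,
                     double f1, double f2) {
    if (g1 > g2) {
      std::swap(g1, g2);
      std::swap(p1, p2);
      std::swap(f1, f2);
    }
    const uint64_t key = (uint64_t)g1 * 0x100000000ULL + (uint64_t)g2;
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    const double t = f1 / (f1 - f2);  // f measured relative to the level
    const int id = (int)vx.size();
    vx.push_back(p1[0] + t * (p2[0] - p1[0]));
    vy.push_back(p1[1] + t * (p2[1] - p1[1]));
    vz.push_back(p1[2] + t * (p2[2] - p1[2]));
    edgeVert[key] = id;
    return id;
  }

  void add_tri(int a, int b, int c, const double *inPt, const double *outPt) {
    // orient so the normal points from the inside (f < 0) to the outside
    const double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    const double wx2 = vx[c] - vx[a], wy2 = vy[c] - vy[a], wz2 = vz[c] - vz[a];
    const double nx = uy * wz2 - uz * wy2;
    const double ny = uz * wx2 - ux * wz2;
    const double nz = ux * wy2 - uy * wx2;
    const double dx = outPt[0] - inPt[0], dy = outPt[1] - inPt[1],
                 dz = outPt[2] - inPt[2];
    if (nx * dx + ny * dy + nz * dz < 0) std::swap(b, c);
    tri.push_back(a);
    tri.push_back(b);
    tri.push_back(c);
  }
};

}  // namespace

// [[Rcpp::export]]
List mt_isosurface(NumericVector field, IntegerVector dims,
                   NumericVector origin, double spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) { return i + nx * (j + ny * k); };

  // cube corner offsets indexed by bits (x, y, z)
  const int off[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                         {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  // 5-tet split; even cubes use central tet {0, 3, 5, 6}, odd the mirror
  const int TET_EVEN[5][4] = {
      {0, 3, 5, 6}, {1, 0, 3, 5}, {2, 0, 3, 6}, {4, 0, 5, 6}, {7, 3, 5, 6}};
  const int TET_ODD[5][4] = {
      {1, 2, 4, 7}, {0, 1, 2, 4}, {3, 1, 2, 7}, {5, 1, 4, 7}, {6, 2, 4, 7}};

  MeshAcc acc;
  double cp[8][3];
  double cf[8];
  int cg[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          cg[c] = gid(ii, jj, kk);
          double f = field[cg[c]] - level;
          if (f == 0.0) f = 1e-12;  // avoid vertices exactly on the level
          cf[c] = f;
          cp[c][0] = origin[0] + spacing * ii;
          cp[c][1] = origin[1] + spacing * jj;
          cp[c][2] = origin[2] + spacing * kk;
          if (f < 0) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        const bool odd = ((i + j + k) & 1) != 0;
        const int(*TT)[4] = odd ? TET_ODD : TET_EVEN;
        for (int t = 0; t < 5; ++t) {
          const int *tv = TT[t];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) {
            if (cf[tv[s]] < 0) ins[ni++] = tv[s]; else outs[no++] = tv[s];
          }
          if (ni == 0 || ni == 4) continue;
          auto V = [&](int a, int b) {
            return acc.vertex_on_edge(cg[a], cg[b], cp[a], cp[b], cf[a], cf[b]);
          };
          if (ni == 1) {
            const int a = ins[0];
            acc.add_tri(V(a, outs[0]), V(a, outs[1]), V(a, outs[2]),
                        cp[a], cp[outs[0]]);
          } else if (ni == 3) {
            const int a = outs[0];
            acc.add_tri(V(ins[0], a), V(ins[1], a), V(ins[2], a),
                        cp[ins[0]], cp[a]);
          } else {  // 2 in, 2 out: quad split into two triangles
            const int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            const int vac = V(a, c), vad = V(a, d), vbc = V(b, c), vbd = V(b, d);
            acc.add_tri(vac, vad, vbd, cp[a], cp[c]);
            acc.add_tri(vac, vbd, vbc, cp[a], cp[c]);
          }
        }
      }
    }
  }

  const int nv = (int)acc.vx.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = acc.vx[v];
    verts(v, 1) = acc.vy[v];
    verts(v, 2) = acc.vz[v];
  }
  const int nt = (int)acc.tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t) {
    tris(t, 0) = acc.tri[3 * t] + 1;
    tris(t, 1) = acc.tri[3 * t + 1] + 1;
    tris(t, 2) = acc.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}
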