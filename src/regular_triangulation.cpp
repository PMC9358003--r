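// Incremental Bowyer-Watson construction of the 3D regular (weighted
// Delaunay) triangulation.  Points carry weights w = (radius + probe)^2;
// the conflict predicate is the power-distance (lifted in-sphere) test.
// Degeneracies are assumed to be pre-broken by a deterministic jitter
// applied on the R side; predicates use plain doubles with strict signs.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];   // vertex ids (0-based; 0..3 are the bounding super-tet)
  int nb[4];  // neighbor opposite v[i]; -1 = outside the super-tet
  char alive;
};

// face opposite v[i], ordered so orient3d(f0, f1, f2, v[i]) > 0
// when the tetrahedron is positively oriented
const int FACE[4][3] = {{1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};

inline double orient3d(const double *a, const double *b, const double *c,
                       const double *d) {
  const double bx = b[0] - a[0], by = b[1] - a[1], bz = b[2] - a[2];
  const double cx = c[0] - a[0], cy = c[1] - a[1], cz = c[2] - a[2];
  const double dx = d[0] - a[0], dy = d[1] - a[1], dz = d[2] - a[2];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

inline double det4(double m[4][4]) {
  double r = 0.0;
  for (int c0 = 0; c0 < 4; ++c0) {
    double sub[3][3];
    for (int i = 1; i < 4; ++i) {
      int cc = 0;
      for (int j = 0; j < 4; ++j) {
        if (j == c0) continue;
        sub[i - 1][cc++] = m[i][j];
      }
    }
    const double d3 = sub[0][0] * (sub[1][1] * sub[2][2] - sub[1][2] * sub[2][1]) -
                      sub[0][1] * (sub[1][0] * sub[2][2] - sub[1][2] * sub[2][0]) +
                      sub[0][2] * (sub[1][0] * sub[2][1] - sub[1][1] * sub[2][0]);
    r += ((c0 % 2 == 0) ? 1.0 : -1.0) * m[0][c0] * d3;
  }
  return r;
}

struct Builder {
  std::vector<double> P;  // 3 * nv coordinates
  std::vector<double> W;  // weights
  std::vector<Tet> T;
  std::vector<int> mark;  // conflict-region stamps
  int stamp = 0;
  int lastTet = 0;
  double conflictSign = 1.0;  // calibrated at start-up
  int walkCounter = 0;

  const double *pt(int i) const { return &P[3 * i]; }

  // power in-sphere determinant of point q against tet t;
  // conflictSign * det > 0  <=>  q lies inside the orthosphere of t
  double power_det(int t, const double *q, double qw) const {
    double m[4][4];
    for (int i = 0; i < 4; ++i) {
      const double *p = pt(T[t].v[i]);
      const double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
      m[i][0] = dx;
      m[i][1] = dy;
      m[i][2] = dz;
      m[i][3] = dx * dx + dy * dy + dz * dz - W[T[t].v[i]] + qw;
    }
    return det4(m);
  }

  bool in_conflict(int t, const double *q, double qw) const {
    return conflictSign * power_det(t, q, qw) > 0.0;
  }

  // visibility walk from lastTet toward q; returns a tet containing q
  int locate(const double *q) {
    int cur = lastTet;
    if (!T[cur].alive) {
      for (int i = (int)T.size() - 1; i >= 0; --i)
        if (T[i].alive) { cur = i; break; }
    }
    const int maxSteps = (int)T.size() * 4 + 64;
    int prev = -1;
    for (int step = 0; step < maxSteps; ++step) {
      bool moved = false;
      const int off = walkCounter++;
      for (int k = 0; k < 4; ++k) {
        const int i = (k + off) & 3;
        const int nb = T[cur].nb[i];
        if (nb < 0 || nb == prev) continue;
        const double o = orient3d(pt(T[cur].v[FACE[i][0]]),
                                  pt(T[cur].v[FACE[i][1]]),
                                  pt(T[cur].v[FACE[i][2]]), q);
        if (o < 0.0) {
          prev = cur;
          cur = nb;
          moved = true;
          break;
        }
      }
      if (!moved) return cur;
    }
    return -1;  // walk failed (should not happen after jitter)
  }

  // grow the conflict region from seed; returns region tets and boundary faces
  void conflict_region(int seed, const double *q, double qw,
                       std::vector<int> &region,
                       std::vector<std::pair<int, int>> &boundary) {
    ++stamp;
    region.clear();
    boundary.clear();
    std::vector<int> stack{seed};
    mark[seed] = stamp;
    while (!stack.empty()) {
      const int t = stack.back();
      stack.pop_back();
      region.push_back(t);
      for (int i = 0; i < 4; ++i) {
        const int nb = T[t].nb[i];
        if (nb >= 0 && (int)mark.size() <= nb) mark.resize(T.size(), 0);
        if (nb >= 0 && mark[nb] == stamp) continue;
        if (nb >= 0 && in_conflict(nb, q, qw)) {
          mark[nb] = stamp;
          stack.push_back(nb);
        } else {
          boundary.emplace_back(t, i);
        }
      }
    }
  }

  // force-add extra tets into the marked region and recompute boundary
  void recollect_boundary(std::vector<int> &region,
                          std::vector<std::pair<int, int>> &boundary) {
    boundary.clear();
    std::vector<int> out;
    for (int t : region) {
      for (int i = 0; i < 4; ++i) {
        const int nb = T[t].nb[i];
        if (nb >= 0 && mark[nb] == stamp) continue;
        boundary.emplace_back(t, i);
      }
    }
  }

  // true on success, false if the point is redundant (hidden)
  bool insert(int vid) {
    const double *q = pt(vid);
    const double qw = W[vid];
    int loc = locate(q);
    if (loc < 0) {
      // fallback: exhaustive conflict scan
      loc = -1;
      for (int t = 0; t < (int)T.size(); ++t)
        if (T[t].alive && in_conflict(t, q, qw)) { loc = t; break; }
      if (loc < 0) return false;
    } else if (!in_conflict(loc, q, qw)) {
      return false;  // hidden / redundant point
    }

    std::vector<int> region;
    std::vector<std::pair<int, int>> boundary;
    conflict_region(loc, q, qw, region, boundary);

    // ensure every new tet is positively oriented; if a boundary face is
    // (near-)coplanar with q, absorb its outer neighbor into the region
    for (int attempt = 0; attempt < 64; ++attempt) {
      bool ok = true;
      for (auto &bf : boundary) {
        const Tet &R = T[bf.first];
        const int *f = FACE[bf.second];
        const double o = orient3d(pt(R.v[f[0]]), pt(R.v[f[1]]), pt(R.v[f[2]]), q);
        if (o <= 0.0) {
          const int nb = R.nb[bf.second];
          if (nb < 0) return false;  // cannot flatten against the super-tet
          if ((int)mark.size() <= nb) mark.resize(T.size(), 0);
          if (mark[nb] != stamp) {
            mark[nb] = stamp;
            region.push_back(nb);
          }
          ok = false;
        }
      }
      if (ok) break;
      recollect_boundary(region, boundary);
      if (attempt == 63) return false;
    }

    // retire region tets
    for (int t : region) T[t].alive = 0;

    // build one new tet per boundary face, wiring neighbors
    std::unordered_map<uint64_t, std::pair<int, int>> open;  // edge -> (tet, face)
    open.reserve(boundary.size() * 3);
    int firstNew = -1;
    for (auto &bf : boundary) {
      const Tet &R = T[bf.first];
      const int *f = FACE[bf.second];
      const int a = R.v[f[0]], b = R.v[f[1]], c = R.v[f[2]];
      const int outer = R.nb[bf.second];
      Tet nt;
      nt.v[0] = a; nt.v[1] = b; nt.v[2] = c; nt.v[3] = vid;
      nt.nb[0] = -9; nt.nb[1] = -9; nt.nb[2] = -9; nt.nb[3] = outer;
      nt.alive = 1;
      const int id = (int)T.size();
      T.push_back(nt);
      mark.push_back(0);
      if (firstNew < 0) firstNew = id;
      if (outer >= 0) {
        for (int j = 0; j < 4; ++j)
          if (T[outer].nb[j] == bf.first) { T[outer].nb[j] = id; break; }
      }
      // side faces contain vid and one edge of (a, b, c)
      const int edges[3][2] = {{b, c}, {a, c}, {a, b}};  // opposite a, b, c
      for (int s = 0; s < 3; ++s) {
        const int u = std::min(edges[s][0], edges[s][1]);
        const int w2 = std::max(edges[s][0], edges[s][1]);
        const uint64_t key = (uint64_t)u * 0x100000000ULL + (uint64_t)w2;
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = {id, s};
        } else {
          T[id].nb[s] = it->second.first;
          T[it->second.first].nb[it->second.second] = id;
          open.erase(it);
        }
      }
    }
    lastTet = firstNew;
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
List rt_build(NumericMatrix pts, NumericVector weights) {
  const int n = pts.nrow();
  if (n < 5) stop("need at least 5 points");

  Builder B;
  B.P.resize(3 * (n + 4));
  B.W.resize(n + 4);

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      const double v = pts(i, k);
      B.P[3 * (i + 4) + k] = v;
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
      B.W[i + 4] = weights[i];
    }
  double diag = 0.0, ctr[3];
  for (int k = 0; k < 3; ++k) {
    diag += (hi[k] - lo[k]) * (hi[k] - lo[k]);
    ctr[k] = 0.5 * (lo[k] + hi[k]);
  }
  diag = std::sqrt(diag);
  const double R = 1000.0 * (diag + 1.0);
  const double sv[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};
  for (int i = 0; i < 4; ++i) {
    for (int k = 0; k < 3; ++k) B.P[3 * i + k] = ctr[k] + 3.0 * R * sv[i][k];
    B.W[i] = 0.0;
  }
  Tet t0;
  t0.v[0] = 0; t0.v[1] = 1; t0.v[2] = 2; t0.v[3] = 3;
  t0.nb[0] = t0.nb[1] = t0.nb[2] = t0.nb[3] = -1;
  t0.alive = 1;
  if (orient3d(B.pt(0), B.pt(1), B.pt(2), B.pt(3)) < 0) {
    std::swap(t0.v[0], t0.v[1]);
  }
  B.T.push_back(t0);
  B.mark.push_back(0);

  // calibrate the conflict-predicate sign with a point certainly inside
  {
    double q[3] = {ctr[0], ctr[1], ctr[2]};
    const double d0 = B.power_det(0, q, 0.0);
    B.conflictSign = (d0 > 0) ? 1.0 : -1.0;
  }

  std::vector<int> redundant;
  for (int i = 0; i < n; ++i) {
    if (!B.insert(i + 4)) redundant.push_back(i + 1);
  }

  // collect finite tets (no super-tet vertex), renumber, fix neighbors
  std::vector<int> newId(B.T.size(), -1);
  std::vector<int> keep;
  for (int t = 0; t < (int)B.T.size(); ++t) {
    if (!B.T[t].alive) continue;
    bool finite = true;
    for (int i = 0; i < 4; ++i)
      if (B.T[t].v[i] < 4) { finite = false; break; }
    if (finite) {
      newId[t] = (int)keep.size();
      keep.push_back(t);
    }
  }
  const int m = (int)keep.size();
  IntegerMatrix tv(m, 4), tn(m, 4);
  NumericMatrix oc(m, 3);
  NumericVector sqor(m), vol(m);

  for (int r = 0; r < m; ++r) {
    const Tet &t = B.T[keep[r]];
    for (int i = 0; i < 4; ++i) {
      tv(r, i) = t.v[i] - 3;  // 1-based atom ids
      const int nb = t.nb[i];
      tn(r, i) = (nb >= 0 && newId[nb] >= 0) ? (newId[nb] + 1) : 0;
    }
    // orthocenter: solve 2 (v_j - v_0) . z = (|v_j|^2 - w_j) - (|v_0|^2 - w_0)
    const double *a = B.pt(t.v[0]);
    double A[3][3], rhs[3];
    const double la = a[0] * a[0] + a[1] * a[1] + a[2] * a[2] - B.W[t.v[0]];
    for (int j = 0; j < 3; ++j) {
      const double *p = B.pt(t.v[j + 1]);
      for (int k = 0; k < 3; ++k) A[j][k] = 2.0 * (p[k] - a[k]);
      rhs[j] = (p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - B.W[t.v[j + 1]]) - la;
    }
    const double det =
        A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
        A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
        A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    double z[3];
    for (int k = 0; k < 3; ++k) {
      double M[3][3];
      for (int j = 0; j < 3; ++j)
        for (int c = 0; c < 3; ++c) M[j][c] = (c == k) ? rhs[j] : A[j][c];
      const double dk =
          M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
          M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
          M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
      z[k] = dk / det;
    }
    oc(r, 0) = z[0]; oc(r, 1) = z[1]; oc(r, 2) = z[2];
    const double dx = z[0] - a[0], dy = z[1] - a[1], dz = z[2] - a[2];
    sqor[r] = dx * dx + dy * dy + dz * dz - B.W[t.v[0]];
    vol[r] = orient3d(B.pt(t.v[0]), B.pt(t.v[1]), B.pt(t.v[2]),
                      B.pt(t.v[3])) / 6.0;
  }

  return List::create(_["tets"] = tv, _["neighbors"] = tn,
                      _["orthocenter"] = oc, _["sq_orthoradius"] = sqor,
                      _["volume"] = vol,
                      _["redundant"] = IntegerVector(redundant.begin(),
                                                     redundant.end()));
}
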