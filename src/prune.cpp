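// Skeleton pruning: scores the all-pairs shortest paths by
// length^2 / tortuousness (length = number of edges) and returns the best.
//
// metric 1 (default): shortest paths under the supplied edge costs
//   (Euclidean lengths when no costs are given), computed by Dijkstra per
//   source; ties are broken deterministically by preferring the smaller
//   predecessor id at equal distance.  The score always uses the Euclidean
//   length of the path, whatever metric routed it.
// metric 0: unweighted (edge-count) shortest paths; for each unordered pair
//   the lexicographically smallest shortest path is used, which an
//   independent oracle can reproduce from a distance matrix alone.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <climits>

using namespace Rcpp;

// [[Rcpp::export]]
List rt_prune(IntegerMatrix edges, NumericMatrix pos, double eps,
              int metric, NumericVector cost) {
  const int n = pos.nrow();
  const bool haveCost = cost.size() == edges.nrow();
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    const double dx = pos(a, 0) - pos(b, 0);
    const double dy = pos(a, 1) - pos(b, 1);
    const double dz = pos(a, 2) - pos(b, 2);
    const double len = haveCost ? cost[e]
                                : std::sqrt(dx * dx + dy * dy + dz * dz);
    adj[a].push_back({b, len});
    adj[b].push_back({a, len});
  }
  for (int i = 0; i < n; ++i) std::sort(adj[i].begin(), adj[i].end());

  // per-source shortest-path structures
  std::vector<int> hopdist;            // metric 0: full n x n matrix
  std::vector<int> parent((size_t)n * n, -1);  // metric 1: parent trees
  if (metric == 0) hopdist.assign((size_t)n * n, INT_MAX / 2);

  if (metric == 0) {
    std::vector<int> bfsq(n);
    for (int s = 0; s < n; ++s) {
      int *d = &hopdist[(size_t)s * n];
      int head = 0, tail = 0;
      d[s] = 0;
      bfsq[tail++] = s;
      while (head < tail) {
        const int u = bfsq[head++];
        for (auto &pr : adj[u])
          if (d[pr.first] == INT_MAX / 2) {
            d[pr.first] = d[u] + 1;
            bfsq[tail++] = pr.first;
          }
      }
    }
  } else {
    std::vector<double> dist(n);
    typedef std::pair<double, int> QE;
    for (int s = 0; s < n; ++s) {
      int *par = &parent[(size_t)s * n];
      std::fill(dist.begin(), dist.end(), R_PosInf);
      std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
      dist[s] = 0.0;
      par[s] = s;
      pq.push({0.0, s});
      while (!pq.empty()) {
        const QE top = pq.top();
        pq.pop();
        const int u = top.second;
        if (top.first > dist[u]) continue;
        for (auto &pr : adj[u]) {
          const double nd = top.first + pr.second;
          if (nd < dist[pr.first]) {
            dist[pr.first] = nd;
            par[pr.first] = u;
            pq.push({nd, pr.first});
          }
        }
      }
    }
  }

  double bestScore = -1.0, bestTort = 0.0, bestPlen = -1.0;
  int bestLen = -1, bestS = -1, bestT = -1;
  std::vector<int> bestPath, path;

  for (int s = 0; s < n; ++s) {
    const int *dS = (metric == 0) ? &hopdist[(size_t)s * n] : nullptr;
    const int *parS = (metric == 1) ? &parent[(size_t)s * n] : nullptr;
    for (int t = s + 1; t < n; ++t) {
      path.clear();
      if (metric == 0) {
        const int L = dS[t];
        if (L >= INT_MAX / 2 || L == 0) continue;
        // lexicographically smallest shortest path from s to t
        const int *dT = &hopdist[(size_t)t * n];
        path.push_back(s);
        int cur = s;
        while (cur != t) {
          for (auto &pr : adj[cur]) {
            if (dT[pr.first] == dT[cur] - 1) {
              cur = pr.first;
              break;
            }
          }
          path.push_back(cur);
        }
      } else {
        if (parS[t] < 0) continue;  // unreachable
        int cur = t;
        while (cur != s && (int)path.size() <= n) {
          path.push_back(cur);
          cur = parS[cur];
        }
        if (cur != s) continue;  // defensive: malformed parent chain
        path.push_back(s);
        std::reverse(path.begin(), path.end());
      }
      const int L = (int)path.size() - 1;
      if (L == 0) continue;
      // path length entering the score: edge count for the hop metric,
      // summed Euclidean edge length for the geometric metric
      double plen = (double)L;
      if (metric == 1) {
        plen = 0.0;
        for (int k = 1; k <= L; ++k) {
          const int a = path[k - 1], b = path[k];
          const double dx = pos(a, 0) - pos(b, 0);
          const double dy = pos(a, 1) - pos(b, 1);
          const double dz = pos(a, 2) - pos(b, 2);
          plen += std::sqrt(dx * dx + dy * dy + dz * dz);
        }
      }

      // tortuousness: mean node distance to the line through the endpoints
      const double ax = pos(s, 0), ay = pos(s, 1), az = pos(s, 2);
      double ux = pos(t, 0) - ax, uy = pos(t, 1) - ay, uz = pos(t, 2) - az;
      const double un = std::sqrt(ux * ux + uy * uy + uz * uz);
      double tort;
      if (un < 1e-12) {
        tort = R_PosInf;  // coincident endpoints: never optimal
      } else {
        ux /= un; uy /= un; uz /= un;
        double acc = 0.0;
        for (int v : path) {
          const double px = pos(v, 0) - ax, py = pos(v, 1) - ay,
                       pz = pos(v, 2) - az;
          const double proj = px * ux + py * uy + pz * uz;
          const double rx = px - proj * ux, ry = py - proj * uy,
                       rz = pz - proj * uz;
          acc += std::sqrt(rx * rx + ry * ry + rz * rz);
        }
        tort = acc / (double)path.size();
      }
      const double score = plen * plen / std::max(tort, eps);
      // tie-breaks: higher score, then longer path, then smaller endpoints
      if (score > bestScore ||
          (score == bestScore &&
           (plen > bestPlen ||
            (plen == bestPlen && (s < bestS ||
                                  (s == bestS && t < bestT)))))) {
        bestScore = score;
        bestLen = L;
        bestPlen = plen;
        bestTort = tort;
        bestS = s;
        bestT = t;
        bestPath = path;
      }
    }
  }

  if (bestS < 0) return List::create(_["path"] = IntegerVector(0));
  IntegerVector out(bestPath.size());
  for (size_t i = 0; i < bestPath.size(); ++i) out[i] = bestPath[i] + 1;
  return List::create(_["path"] = out, _["score"] = bestScore,
                      _["length"] = bestLen, _["metric_length"] = bestPlen,
                      _["tortuousness"] = bestTort);
}
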