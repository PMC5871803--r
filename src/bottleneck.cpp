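// Exact bottleneck distance between two H0 persistence diagrams.
//
// Points are (birth, death) pairs; the ground metric is L-infinity and an
// unmatched point may be matched to the diagonal at cost persistence / 2.
// The distance is found by binary search over the finite candidate set
// {0} U {pairwise L-inf distances} U {persistences / 2}, testing each
// candidate cost c for the existence of a matching within cost c.
//
// Feasibility at cost c reduces (Mendelsohn-Dulmage) to two saturation
// checks: the points of A with persistence/2 > c ("forced") must be
// saturated by a matching into B using edges of L-inf cost <= c, and
// symmetrically for B. Each check runs Hopcroft-Karp.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

const int INF = std::numeric_limits<int>::max();

// Hopcroft-Karp maximum matching; returns matching size.
struct HopcroftKarp {
  int nL, nR;
  std::vector<std::vector<int>> adj;
  std::vector<int> matchL, matchR, dist;

  HopcroftKarp(int nL_, int nR_) : nL(nL_), nR(nR_), adj(nL_) {}

  void addEdge(int l, int r) { adj[l].push_back(r); }

  bool bfs() {
    std::queue<int> q;
    dist.assign(nL, INF);
    for (int l = 0; l < nL; ++l)
      if (matchL[l] < 0) { dist[l] = 0; q.push(l); }
    bool found = false;
    while (!q.empty()) {
      int l = q.front(); q.pop();
      for (int r : adj[l]) {
        int l2 = matchR[r];
        if (l2 < 0) found = true;
        else if (dist[l2] == INF) { dist[l2] = dist[l] + 1; q.push(l2); }
      }
    }
    return found;
  }

  bool dfs(int l) {
    for (int r : adj[l]) {
      int l2 = matchR[r];
      if (l2 < 0 || (dist[l2] == dist[l] + 1 && dfs(l2))) {
        matchL[l] = r; matchR[r] = l;
        return true;
      }
    }
    dist[l] = INF;
    return false;
  }

  int maxMatching() {
    matchL.assign(nL, -1);
    matchR.assign(nR, -1);
    int size = 0;
    while (bfs())
      for (int l = 0; l < nL; ++l)
        if (matchL[l] < 0 && dfs(l)) ++size;
    return size;
  }
};

inline double linf(double b1, double d1, double b2, double d2) {
  return std::max(std::fabs(b1 - b2), std::fabs(d1 - d2));
}

// Can every forced point of `from` be matched into `to` within cost c?
bool saturates(const NumericMatrix& from, const NumericMatrix& to, double c) {
  std::vector<int> forced;
  for (int i = 0; i < from.nrow(); ++i)
    if ((from(i, 0) - from(i, 1)) / 2.0 > c) forced.push_back(i);
  if (forced.empty()) return true;
  if (to.nrow() == 0) return false;
  HopcroftKarp hk((int)forced.size(), to.nrow());
  for (size_t k = 0; k < forced.size(); ++k)
    for (int j = 0; j < to.nrow(); ++j)
      if (linf(from(forced[k], 0), from(forced[k], 1), to(j, 0), to(j, 1)) <= c)
        hk.addEdge((int)k, j);
  return hk.maxMatching() == (int)forced.size();
}

bool feasible(const NumericMatrix& a, const NumericMatrix& b, double c) {
  return saturates(a, b, c) && saturates(b, a, c);
}

} // namespace

// [[Rcpp::export(name = ".bottleneckCpp")]]
double bottleneckCpp(NumericMatrix a, NumericMatrix b) {
  const int nA = a.nrow(), nB = b.nrow();
  if (nA == 0 && nB == 0) return 0.0;

  std::vector<double> cand;
  cand.push_back(0.0);
  for (int i = 0; i < nA; ++i) cand.push_back((a(i, 0) - a(i, 1)) / 2.0);
  for (int j = 0; j < nB; ++j) cand.push_back((b(j, 0) - b(j, 1)) / 2.0);
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < nB; ++j)
      cand.push_back(linf(a(i, 0), a(i, 1), b(j, 0), b(j, 1)));
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  // smallest candidate cost at which a matching exists
  size_t lo = 0, hi = cand.size() - 1;
  while (lo < hi) {
    size_t mid = lo + (hi - lo) / 2;
    if (feasible(a, b, cand[mid])) hi = mid; else lo = mid + 1;
  }
  return cand[lo];
}
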