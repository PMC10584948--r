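#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Core distances and mutual-reachability minimum spanning tree for
// HDBSCAN. Brute-force O(n^2) distance evaluation with O(n) memory:
// adequate for localization tables of the size a single nucleus yields
// (~1e4 points) and free of spatial-index edge cases.
//
// Core distance of point i = distance to its k-th nearest neighbour,
// counting the point itself as the first (distance 0), k = min_samples.
// Mutual reachability d_mr(i,j) = max(core_i, core_j, d(i,j)).

// [[Rcpp::export]]
NumericVector core_distances(NumericMatrix xy, int min_samples) {
  const int n = xy.nrow();
  NumericVector core(n);
  if (min_samples <= 1) return core;  // self is nearest; distance 0
  const int k = min_samples - 1;      // k-th other point
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = xy(i, 0); y[i] = xy(i, 1); }
  for (int i = 0; i < n; ++i) {
    std::priority_queue<double> heap;  // max-heap of k smallest d2
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if ((int)heap.size() < k) heap.push(d2);
      else if (d2 < heap.top()) { heap.pop(); heap.push(d2); }
    }
    core[i] = heap.empty() ? 0.0 : std::sqrt(heap.top());
  }
  return core;
}

// Prim's algorithm on the complete mutual-reachability graph.
// Returns (n-1) x 3 matrix: 1-based endpoints and the edge weight.
// [[Rcpp::export]]
NumericMatrix mutual_reachability_mst(NumericMatrix xy,
                                      NumericVector core) {
  const int n = xy.nrow();
  NumericMatrix edges(std::max(n - 1, 0), 3);
  if (n <= 1) return edges;
  std::vector<double> x(n), y(n), cd(n), best(n,
      std::numeric_limits<double>::infinity());
  std::vector<int> from(n, 0);
  std::vector<bool> used(n, false);
  for (int i = 0; i < n; ++i) {
    x[i] = xy(i, 0); y[i] = xy(i, 1); cd[i] = core[i];
  }
  int cur = 0;
  used[0] = true;
  for (int m = 0; m < n - 1; ++m) {
    // relax edges from `cur`
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      double dx = x[cur] - x[j], dy = y[cur] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      double w = std::max(d, std::max(cd[cur], cd[j]));
      if (w < best[j]) { best[j] = w; from[j] = cur; }
    }
    // pick closest unused
    int nxt = -1;
    double bw = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      if (!used[j] && best[j] < bw) { bw = best[j]; nxt = j; }
    }
    edges(m, 0) = from[nxt] + 1;
    edges(m, 1) = nxt + 1;
    edges(m, 2) = bw;
    used[nxt] = true;
    cur = nxt;
  }
  return edges;
}

// Single-linkage agglomeration of the MST (edges sorted ascending by
// weight outside). Returns scipy-style merge table: for step m (1..n-1),
// children node ids (leaves 1..n, internal n+1..2n-1), the merge
// distance and the merged size.
// [[Rcpp::export]]
List single_linkage_tree(IntegerVector ia, IntegerVector ib,
                         NumericVector w, int n) {
  int m = ia.size();
  IntegerVector left(m), right(m), size(m);
  NumericVector dist(m);
  std::vector<int> parent(2 * n - 1 + 1);  // union-find over node ids
  std::vector<int> node_of(2 * n - 1 + 1); // root -> current node id
  std::vector<int> sz(2 * n - 1 + 1, 1);
  for (int i = 0; i <= 2 * n - 1; ++i) { parent[i] = i; node_of[i] = i; }
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };
  for (int e = 0; e < m; ++e) {
    int ra = find(ia[e]), rb = find(ib[e]);
    int node = n + e + 1;
    left[e] = node_of[ra];
    right[e] = node_of[rb];
    dist[e] = w[e];
    size[e] = sz[ra] + sz[rb];
    parent[ra] = node; parent[rb] = node; parent[node] = node;
    node_of[node] = node;
    sz[node] = size[e];
  }
  return List::create(_["left"] = left, _["right"] = right,
                      _["dist"] = dist, _["size"] = size);
}
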