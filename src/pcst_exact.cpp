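#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact prize-collecting Steiner tree by enumeration over node subsets.
//
// For a fixed node set S the cheapest subtree spanning S is the minimum
// spanning tree of the induced subgraph G[S] (edge costs are nonnegative),
// so the global optimum over subtrees is the optimum over node subsets
// whose induced subgraph is connected, plus the empty tree.
//
// Nodes are 0-based indices ordered by node identifier, which makes the
// lexicographic tie-break on sorted node-id lists a lexicographic
// comparison of ascending index vectors.

static double prim_mst(const std::vector<double> &adj, int n,
                       const std::vector<int> &nodes, bool &connected) {
  int k = (int)nodes.size();
  connected = true;
  if (k <= 1) return 0.0;
  std::vector<double> dist(k, R_PosInf);
  std::vector<bool> used(k, false);
  dist[0] = 0.0;
  double total = 0.0;
  for (int it = 0; it < k; ++it) {
    int u = -1;
    double dmin = R_PosInf;
    for (int i = 0; i < k; ++i)
      if (!used[i] && dist[i] < dmin) { dmin = dist[i]; u = i; }
    if (u < 0) { connected = false; return R_PosInf; }
    used[u] = true;
    total += dist[u];
    for (int i = 0; i < k; ++i)
      if (!used[i]) {
        double c = adj[(size_t)nodes[u] * n + nodes[i]];
        if (c < dist[i]) dist[i] = c;
      }
  }
  return total;
}

// true if `a` is lexicographically smaller than `b` (both ascending)
static bool lex_smaller(const std::vector<int> &a, const std::vector<int> &b) {
  size_t L = std::min(a.size(), b.size());
  for (size_t i = 0; i < L; ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return a.size() < b.size();
}

// [[Rcpp::export]]
List pcst_exact_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                    NumericVector cost, NumericVector penalty, double beta,
                    double eps = 1e-9) {
  if (n > 30) stop("node count too large for subset enumeration");
  int m = edge_i.size();
  std::vector<double> adj((size_t)n * n, R_PosInf);
  for (int e = 0; e < m; ++e) {
    int a = edge_i[e], b = edge_j[e];
    double c = cost[e];
    if (c < adj[(size_t)a * n + b]) {
      adj[(size_t)a * n + b] = c;
      adj[(size_t)b * n + a] = c;
    }
  }
  double total_pen = 0.0;
  for (int v = 0; v < n; ++v) total_pen += penalty[v];

  double best = beta * total_pen;  // empty tree pays every penalty
  std::vector<int> best_nodes;     // empty

  long long nsub = 1LL << n;
  std::vector<int> nodes;
  nodes.reserve(n);
  for (long long mask = 1; mask < nsub; ++mask) {
    nodes.clear();
    double pin = 0.0;
    for (int v = 0; v < n; ++v)
      if ((mask >> v) & 1LL) { nodes.push_back(v); pin += penalty[v]; }
    bool connected;
    double mstcost = prim_mst(adj, n, nodes, connected);
    if (!connected) continue;
    double obj = beta * (total_pen - pin) + mstcost;
    if (obj < best - eps) {
      best = obj;
      best_nodes = nodes;
    } else if (obj <= best + eps) {
      if (obj < best) best = obj;
      if (lex_smaller(nodes, best_nodes)) best_nodes = nodes;
    }
  }

  // recover MST edges of the winning subset with a deterministic Prim order
  std::vector<int> ea, eb;
  int k = (int)best_nodes.size();
  if (k > 1) {
    std::vector<double> dist(k, R_PosInf);
    std::vector<int> parent(k, -1);
    std::vector<bool> used(k, false);
    dist[0] = 0.0;
    for (int it = 0; it < k; ++it) {
      int u = -1;
      double dmin = R_PosInf;
      for (int i = 0; i < k; ++i)
        if (!used[i] && dist[i] < dmin) { dmin = dist[i]; u = i; }
      used[u] = true;
      if (parent[u] >= 0) {
        ea.push_back(best_nodes[parent[u]]);
        eb.push_back(best_nodes[u]);
      }
      for (int i = 0; i < k; ++i)
        if (!used[i]) {
          double c = adj[(size_t)best_nodes[u] * n + best_nodes[i]];
          if (c < dist[i]) { dist[i] = c; parent[i] = u; }
        }
    }
  }

  return List::create(_["nodes"] = wrap(best_nodes),
                      _["edge_a"] = wrap(ea), _["edge_b"] = wrap(eb),
                      _["objective"] = best);
}
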