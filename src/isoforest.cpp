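#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

// average unsuccessful-search path length in a BST of m nodes
static double avg_path(int m) {
  if (m <= 1) return 0.0;
  if (m == 2) return 1.0;
  double h = std::log((double)(m - 1)) + 0.5772156649015329;
  return 2.0 * h - 2.0 * (m - 1) / (double)m;
}

struct Node {
  int dim;        // -1 for external
  double split;
  int left, right;
  int size;       // external node size
};

static int build(std::vector<Node>& nodes,
                 const NumericMatrix& X,
                 std::vector<int>& idx, int lo, int hi,
                 int depth, int max_depth, std::mt19937& rng) {
  int n = hi - lo;
  int me = (int)nodes.size();
  nodes.push_back(Node());
  if (n <= 1 || depth >= max_depth) {
    nodes[me].dim = -1; nodes[me].size = n;
    return me;
  }
  int d = X.ncol();
  // pick a dimension with spread; fall back to external if none
  std::uniform_int_distribution<int> dpick(0, d - 1);
  int dim = -1; double mn = 0, mx = 0;
  for (int attempt = 0; attempt < 2 * d; ++attempt) {
    int cand = dpick(rng);
    double lo_v = X(idx[lo], cand), hi_v = lo_v;
    for (int i = lo; i < hi; ++i) {
      double v = X(idx[i], cand);
      if (v < lo_v) lo_v = v;
      if (v > hi_v) hi_v = v;
    }
    if (hi_v > lo_v) { dim = cand; mn = lo_v; mx = hi_v; break; }
  }
  if (dim < 0) { nodes[me].dim = -1; nodes[me].size = n; return me; }
  std::uniform_real_distribution<double> spick(mn, mx);
  double split = spick(rng);
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], dim) < split) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) { nodes[me].dim = -1; nodes[me].size = n; return me; }
  nodes[me].dim = dim; nodes[me].split = split;
  int l = build(nodes, X, idx, lo, mid, depth + 1, max_depth, rng);
  int r = build(nodes, X, idx, mid, hi, depth + 1, max_depth, rng);
  nodes[me].left = l; nodes[me].right = r;
  return me;
}

static double path_len(const std::vector<Node>& nodes, int root,
                       const NumericMatrix& X, int row) {
  int cur = root, depth = 0;
  while (nodes[cur].dim >= 0) {
    cur = (X(row, nodes[cur].dim) < nodes[cur].split) ? nodes[cur].left
                                                      : nodes[cur].right;
    ++depth;
  }
  return depth + avg_path(nodes[cur].size);
}

//' Isolation-forest anomaly scores
//'
//' Scores in (0, 1); higher means more isolated (anomalous). Standard
//' formulation: random axis-aligned splits, depth limit ceil(log2(n)),
//' score 2^(-E[path]/c(n)).
//'
//' @param X numeric matrix (rows = points).
//' @param n_trees number of trees (default 100).
//' @param seed RNG seed.
//' @return numeric vector of anomaly scores, one per row.
//' @export
// [[Rcpp::export]]
NumericVector isoforest_scores(NumericMatrix X, int n_trees = 100,
                               int seed = 1) {
  int n = X.nrow();
  NumericVector out(n);
  if (n <= 2) { std::fill(out.begin(), out.end(), 0.5); return out; }
  std::mt19937 rng((unsigned)seed);
  int max_depth = (int)std::ceil(std::log2((double)n));
  std::vector<double> acc(n, 0.0);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    int root = build(nodes, X, idx, 0, n, 0, max_depth, rng);
    for (int i = 0; i < n; ++i) acc[i] += path_len(nodes, root, X, i);
  }
  double cn = avg_path(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::pow(2.0, -(acc[i] / n_trees) / cn);
  return out;
}
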