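// Entropy-based binary classification tree (two classes), the shared core of
// the c45_like / rep_tree / random_tree / random forest learners.  Trees are
// returned as flat parallel arrays so R-side pruning can collapse a node by
// setting its feature to -1; per-node training class counts stay available
// for scores.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
#include <stack>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int n0 = 0, n1 = 0;
  int depth = 0;
};

inline double entropy2(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  if (c0 > 0.0) h -= c0 * std::log(c0 / n);
  if (c1 > 0.0) h -= c1 * std::log(c1 / n);
  return h / n;
}

struct Task {
  std::vector<int> idx;
  int depth;
  int slot;
};

} // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int mtry, int min_split,
                   int min_leaf, int max_depth, std::string criterion,
                   int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X/y size mismatch");
  const bool gain_ratio = (criterion == "gainratio");
  std::mt19937 rng(static_cast<unsigned>(seed));
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  std::vector<Node> nodes;
  nodes.reserve(64);
  std::stack<Task> tasks;
  {
    Task root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    root.depth = 0;
    nodes.emplace_back();
    root.slot = 0;
    tasks.push(std::move(root));
  }

  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;

  while (!tasks.empty()) {
    Task t = std::move(tasks.top());
    tasks.pop();
    int c1 = 0;
    for (int i : t.idx) c1 += y[i];
    const int m = static_cast<int>(t.idx.size());
    nodes[t.slot].depth = t.depth;
    nodes[t.slot].n0 = m - c1;
    nodes[t.slot].n1 = c1;
    const int nd_n0 = m - c1, nd_n1 = c1;
    const bool pure = (c1 == 0 || c1 == m);
    if (pure || m < min_split || (max_depth >= 0 && t.depth >= max_depth)) {
      continue; // leaf
    }

    // candidate features: partial Fisher-Yates over a persistent pool
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feats[j], feats[pick(rng)]);
    }
    std::vector<int> cand(feats.begin(), feats.begin() + mtry);
    std::sort(cand.begin(), cand.end()); // deterministic evaluation order

    const double h_parent = entropy2(nd_n0, nd_n1);
    double best_score = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vy(m);
    for (int jj = 0; jj < static_cast<int>(cand.size()); ++jj) {
      const int f = cand[jj];
      for (int i = 0; i < m; ++i) {
        vy[i] = {X(t.idx[i], f), y[t.idx[i]]};
      }
      std::sort(vy.begin(), vy.end());
      if (vy.front().first == vy.back().first) continue;
      int l1 = 0;
      for (int i = 0; i < m - 1; ++i) {
        l1 += vy[i].second;
        if (vy[i].first == vy[i + 1].first) continue;
        const int nl = i + 1, nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const int l0 = nl - l1;
        const int r1 = c1 - l1, r0 = nr - r1;
        const double h_children =
          (nl * entropy2(l0, l1) + nr * entropy2(r0, r1)) / m;
        double gain = h_parent - h_children;
        double score = gain;
        if (gain_ratio) {
          const double split_h = entropy2(nl, nr);
          if (split_h < 1e-12) continue;
          score = gain / split_h;
        }
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vy[i].first + vy[i + 1].first);
        }
      }
    }
    if (best_feat < 0) continue; // no admissible split -> leaf

    Task tl, tr;
    tl.idx.reserve(m);
    tr.idx.reserve(m);
    for (int i : t.idx) {
      if (X(i, best_feat) <= best_thr) tl.idx.push_back(i);
      else tr.idx.push_back(i);
    }
    if (tl.idx.empty() || tr.idx.empty()) continue;
    nodes.emplace_back();
    const int left_slot = static_cast<int>(nodes.size()) - 1;
    nodes.emplace_back();
    const int right_slot = static_cast<int>(nodes.size()) - 1;
    nodes[t.slot].feature = best_feat;
    nodes[t.slot].threshold = best_thr;
    nodes[t.slot].left = left_slot;
    nodes[t.slot].right = right_slot;
    tl.depth = tr.depth = t.depth + 1;
    tl.slot = left_slot;
    tr.slot = right_slot;
    tasks.push(std::move(tr));
    tasks.push(std::move(tl));
  }

  const int nn = static_cast<int>(nodes.size());
  IntegerVector feature(nn), left(nn), right(nn), n0(nn), n1(nn), depth(nn);
  NumericVector threshold(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    n0[i] = nodes[i].n0;
    n1[i] = nodes[i].n1;
    depth[i] = nodes[i].depth;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["n0"] = n0,
                      _["n1"] = n1, _["depth"] = depth);
}

// Route rows of X to their terminal node (feature == -1 marks a leaf, which
// R-side pruning can impose on any internal node). Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_tree_apply(IntegerVector feature, NumericVector threshold,
                             IntegerVector left, IntegerVector right,
                             NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = node + 1;
  }
  return out;
}
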