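// Random-forest classifier for binary outcomes: CART trees with Gini splits,
// bootstrap resampling and per-node feature subsampling (mtry). Authored here
// because no RF implementation ships with the target environment. RNG is a
// self-contained mt19937 stream so results are fully determined by `seed`,
// independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;      // split feature, -1 for leaf
  std::vector<double> thr;    // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf class (0/1), -1 for internal
};

inline double gini(int c1, int n) {
  if (n == 0) return 0.0;
  double p1 = double(c1) / n;
  return 2.0 * p1 * (1.0 - p1);
}

int grow_node(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
              std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
              std::mt19937& rng, std::vector<int>& feat_pool,
              std::vector<double>& importance) {
  const int n = hi - lo;
  int c1 = 0;
  for (int i = lo; i < hi; ++i) c1 += y[idx[i]];
  const int node_id = (int)tree.feat.size();
  tree.feat.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(c1 * 2 > n ? 1 : 0);  // majority, tie -> class 0

  if (c1 == 0 || c1 == n || n < min_node) return node_id;

  const double g_parent = gini(c1, n);
  const int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> pick(j, p - 1);
    std::swap(feat_pool[j], feat_pool[pick(rng)]);
  }

  double best_dec = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int j = 0; j < mtry; ++j) {
    const int f = feat_pool[j];
    for (int i = 0; i < n; ++i) {
      const int s = idx[lo + i];
      vals[i] = {X(s, f), y[s]};
    }
    std::sort(vals.begin(), vals.end());
    int nl = 0, c1l = 0;
    for (int i = 0; i < n - 1; ++i) {
      ++nl;
      c1l += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nr = n - nl, c1r = c1 - c1l;
      const double dec =
          g_parent - (nl * gini(c1l, nl) + nr * gini(c1r, nr)) / n;
      if (dec > best_dec) {
        best_dec = dec;
        best_f = f;
        best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best_f < 0) return node_id;  // no informative split among sampled feats

  importance[best_f] += best_dec * n;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node_id;  // numeric degeneracy guard

  tree.feat[node_id] = best_f;
  tree.thr[node_id] = best_thr;
  tree.pred[node_id] = -1;
  const int l = grow_node(tree, X, y, idx, lo, mid, mtry, min_node, rng,
                          feat_pool, importance);
  tree.left[node_id] = l;
  const int r = grow_node(tree, X, y, idx, mid, hi, mtry, min_node, rng,
                          feat_pool, importance);
  tree.right[node_id] = r;
  return node_id;
}

inline int tree_predict(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feat[node] >= 0)
    node = X(row, t.feat[node]) <= t.thr[node] ? t.left[node] : t.right[node];
  return t.pred[node];
}

List pack_tree(const Tree& t) {
  return List::create(Named("feat") = wrap(t.feat), Named("thr") = wrap(t.thr),
                      Named("left") = wrap(t.left),
                      Named("right") = wrap(t.right),
                      Named("pred") = wrap(t.pred));
}

Tree unpack_tree(const List& l) {
  Tree t;
  t.feat = as<std::vector<int>>(l["feat"]);
  t.thr = as<std::vector<double>>(l["thr"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.pred = as<std::vector<int>>(l["pred"]);
  return t;
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y sizes differ");
  for (int i = 0; i < n; ++i)
    if (y[i] != 0 && y[i] != 1) stop("y must be 0/1");
  if (mtry < 1 || mtry > p) stop("invalid mtry");

  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> draw(0, n - 1);
  std::vector<double> importance(p, 0.0);
  std::vector<int> feat_pool(p);
  for (int f = 0; f < p; ++f) feat_pool[f] = f;

  List trees(ntree);
  IntegerMatrix oob_votes(n, 2);
  std::vector<int> idx;
  std::vector<char> inbag(n);
  for (int b = 0; b < ntree; ++b) {
    idx.resize(n);
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      idx[i] = draw(rng);
      inbag[idx[i]] = 1;
    }
    Tree tree;
    grow_node(tree, X, y, idx, 0, n, mtry, min_node, rng, feat_pool,
              importance);
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) ++oob_votes(i, tree_predict(tree, X, i));
    trees[b] = pack_tree(tree);
  }
  NumericVector imp(p);
  for (int f = 0; f < p; ++f) imp[f] = importance[f] / ntree;
  return List::create(Named("trees") = trees, Named("gini_importance") = imp,
                      Named("oob_votes") = oob_votes, Named("ntree") = ntree,
                      Named("mtry") = mtry, Named("seed") = seed);
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int ntree = trees.size(), n = X.nrow();
  IntegerVector votes1(n);
  for (int b = 0; b < ntree; ++b) {
    Tree t = unpack_tree(trees[b]);
    for (int i = 0; i < n; ++i) votes1[i] += tree_predict(t, X, i);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = votes1[i] * 2 > ntree ? 1 : 0;
  return out;
}
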