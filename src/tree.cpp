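#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <array>
using namespace Rcpp;

// Weighted, depth-limited classification tree with exhaustive axis-aligned
// split search (weighted Gini), plus the discrete AdaBoost round loop.
// Feature orderings are presorted once per ensemble fit so each node's
// split search is a linear scan.
//
// Tree encoding: one row per node with columns
//   0 feature (0-based split feature; -1 for a leaf)
//   1 threshold (go left iff x <= threshold)
//   2 left child row (0-based; -1 for a leaf)
//   3 right child row
//   4 predicted class at the node (weighted majority, ties -> 0)
//   5 weighted fraction of class 1 at the node

typedef std::vector<std::vector<int> > OrderSet;

struct SplitResult {
  int feature;
  double threshold;
  double impurity;
  bool found;
};

static OrderSet presort(const NumericMatrix &X) {
  const int n = X.nrow(), d = X.ncol();
  OrderSet ord(d, std::vector<int>(n));
  for (int j = 0; j < d; ++j) {
    std::vector<int> &o = ord[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double *col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  return ord;
}

static SplitResult best_split(const NumericMatrix &X, const IntegerVector &y,
                              const std::vector<double> &w,
                              const std::vector<char> &inb,
                              const OrderSet &ord, int m, int min_leaf) {
  const int d = X.ncol();
  SplitResult best;
  best.found = false;
  best.impurity = R_PosInf;
  best.feature = -1;
  best.threshold = NA_REAL;

  double W = 0.0, W1 = 0.0;
  for (size_t i = 0; i < inb.size(); ++i) {
    if (!inb[i]) continue;
    W += w[i];
    if (y[i] == 1) W1 += w[i];
  }
  if (W <= 0.0) return best;

  std::vector<int> mem;
  mem.reserve(m);
  for (int j = 0; j < d; ++j) {
    mem.clear();
    for (int i : ord[j])
      if (inb[i]) mem.push_back(i);
    const double *col = &X(0, j);
    double wl = 0.0, wl1 = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      const int k = mem[i];
      wl += w[k];
      if (y[k] == 1) wl1 += w[k];
      if (col[k] == col[mem[i + 1]]) continue;  // split distinct values only
      if (i + 1 < min_leaf || m - i - 1 < min_leaf) continue;
      const double wr = W - wl, wr1 = W1 - wl1;
      double imp = 0.0;
      if (wl > 0.0) imp += wl * (2.0 * (wl1 / wl) * (1.0 - wl1 / wl));
      if (wr > 0.0) imp += wr * (2.0 * (wr1 / wr) * (1.0 - wr1 / wr));
      if (imp < best.impurity - 1e-15) {
        best.impurity = imp;
        best.feature = j;
        best.threshold = 0.5 * (col[k] + col[mem[i + 1]]);
        best.found = true;
      }
    }
  }
  return best;
}

static void grow(const NumericMatrix &X, const IntegerVector &y,
                 const std::vector<double> &w, std::vector<char> &inb,
                 const OrderSet &ord, int m, int depth, int max_depth,
                 int min_leaf, std::vector<std::array<double, 6> > &nodes) {
  double W = 0.0, W1 = 0.0;
  for (size_t i = 0; i < inb.size(); ++i) {
    if (!inb[i]) continue;
    W += w[i];
    if (y[i] == 1) W1 += w[i];
  }
  const double p1 = (W > 0.0) ? W1 / W : 0.0;
  const int me = static_cast<int>(nodes.size());
  nodes.push_back({-1.0, NA_REAL, -1.0, -1.0, (p1 > 0.5) ? 1.0 : 0.0, p1});

  if (depth >= max_depth || p1 <= 0.0 || p1 >= 1.0 || m < 2 * min_leaf)
    return;
  SplitResult s = best_split(X, y, w, inb, ord, m, min_leaf);
  if (!s.found) return;

  std::vector<char> left(inb.size(), 0), right(inb.size(), 0);
  int ml = 0, mr = 0;
  for (size_t i = 0; i < inb.size(); ++i) {
    if (!inb[i]) continue;
    if (X(i, s.feature) <= s.threshold) { left[i] = 1; ++ml; }
    else { right[i] = 1; ++mr; }
  }
  if (ml == 0 || mr == 0) return;
  nodes[me][0] = s.feature;
  nodes[me][1] = s.threshold;
  nodes[me][2] = static_cast<double>(nodes.size());
  grow(X, y, w, left, ord, ml, depth + 1, max_depth, min_leaf, nodes);
  nodes[me][3] = static_cast<double>(nodes.size());
  grow(X, y, w, right, ord, mr, depth + 1, max_depth, min_leaf, nodes);
}

static NumericMatrix pack_nodes(const std::vector<std::array<double, 6> > &nodes) {
  NumericMatrix out(static_cast<int>(nodes.size()), 6);
  for (size_t i = 0; i < nodes.size(); ++i)
    for (int j = 0; j < 6; ++j) out(static_cast<int>(i), j) = nodes[i][j];
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "pred", "prob1");
  return out;
}

static NumericMatrix fit_tree(const NumericMatrix &X, const IntegerVector &y,
                              const std::vector<double> &w,
                              const OrderSet &ord, int max_depth,
                              int min_leaf) {
  std::vector<char> inb(X.nrow(), 1);
  std::vector<std::array<double, 6> > nodes;
  grow(X, y, w, inb, ord, X.nrow(), 0, max_depth, min_leaf, nodes);
  return pack_nodes(nodes);
}

static void tree_predict_into(const NumericMatrix &tree,
                              const NumericMatrix &X, IntegerVector &out) {
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (tree(node, 0) >= 0.0) {
      const int f = static_cast<int>(tree(node, 0));
      node = (X(i, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                        : static_cast<int>(tree(node, 3));
    }
    out[i] = static_cast<int>(tree(node, 4));
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_tree_fit(NumericMatrix X, IntegerVector y, NumericVector w,
                           int max_depth, int min_leaf) {
  const int n = X.nrow();
  if (y.size() != n || w.size() != n) stop("X, y and w must agree in length");
  std::vector<double> wv(w.begin(), w.end());
  return fit_tree(X, y, wv, presort(X), max_depth, min_leaf);
}

// [[Rcpp::export]]
IntegerVector cpp_tree_predict(NumericMatrix tree, NumericMatrix X) {
  IntegerVector out(X.nrow());
  tree_predict_into(tree, X, out);
  return out;
}

// Discrete AdaBoost rounds. Returns the trees, alphas and per-round
// weighted errors; uses R's RNG for the bootstrap refit taken when a round
// has weighted error >= 1/2 (weights reset to uniform first). A round with
// zero error terminates boosting with that learner dominant (alpha = 10).
// [[Rcpp::export]]
List cpp_ada_fit(NumericMatrix X, IntegerVector y, NumericVector init_w,
                 int n_estimators, int max_depth, int min_leaf) {
  const int m = X.nrow();
  OrderSet ord = presort(X);
  std::vector<double> D(init_w.begin(), init_w.end());
  std::vector<NumericMatrix> trees;
  std::vector<double> alphas, errors;
  IntegerVector h(m);

  for (int round = 0; round < n_estimators; ++round) {
    NumericMatrix tree = fit_tree(X, y, D, ord, max_depth, min_leaf);
    tree_predict_into(tree, X, h);
    double eps = 0.0;
    for (int i = 0; i < m; ++i)
      if (h[i] != y[i]) eps += D[i];
    if (eps >= 0.5) {
      // degenerate round: reset weights and refit on a bootstrap resample
      std::fill(D.begin(), D.end(), 1.0 / m);
      NumericMatrix Xb(m, X.ncol());
      IntegerVector yb(m);
      for (int i = 0; i < m; ++i) {
        int pick = static_cast<int>(unif_rand() * m);
        if (pick >= m) pick = m - 1;
        Xb(i, _) = X(pick, _);
        yb[i] = y[pick];
      }
      tree = fit_tree(Xb, yb, D, presort(Xb), max_depth, min_leaf);
      tree_predict_into(tree, X, h);
      eps = 0.0;
      for (int i = 0; i < m; ++i)
        if (h[i] != y[i]) eps += D[i];
      if (eps >= 0.5) continue;  // discard the round entirely
    }
    if (eps == 0.0) {
      trees.push_back(tree);
      alphas.push_back(10.0);
      errors.push_back(0.0);
      break;
    }
    trees.push_back(tree);
    alphas.push_back(0.5 * std::log((1.0 - eps) / eps));
    errors.push_back(eps);
    const double up = std::sqrt((1.0 - eps) / eps);
    const double down = std::sqrt(eps / (1.0 - eps));
    double tot = 0.0;
    for (int i = 0; i < m; ++i) {
      D[i] *= (h[i] != y[i]) ? up : down;
      tot += D[i];
    }
    for (int i = 0; i < m; ++i) D[i] /= tot;
  }
  return List::create(_["trees"] = wrap(trees), _["alphas"] = wrap(alphas),
                      _["errors"] = wrap(errors));
}

// Ensemble margins: sum_n alpha_n * (2 h_n(x) - 1).
// [[Rcpp::export]]
NumericVector cpp_ada_margin(List trees, NumericVector alphas,
                             NumericMatrix X) {
  const int n = X.nrow();
  NumericVector margins(n);
  IntegerVector h(n);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    tree_predict_into(tree, X, h);
    const double a = alphas[t];
    for (int i = 0; i < n; ++i) margins[i] += a * (2 * h[i] - 1);
  }
  return margins;
}
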