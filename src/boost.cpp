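// Second-order gradient boosted trees with logistic loss.
//
// Exact greedy split finding on presorted feature lists, with the standard
// regularized gain
//   gain = 1/2 [ TL1(GL)^2/(HL+lambda) + TL1(GR)^2/(HR+lambda)
//                - TL1(G)^2/(H+lambda) ] - gamma
// where TL1 soft-thresholds the gradient sum by reg_alpha, and leaf weights
// are -TL1(G)/(H+lambda). Shrinkage (eta) is folded into stored leaf values.
// No subsampling, so training is fully deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct TreeNodes {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;    // leaf value (eta already applied)
};

static inline double thresh_l1(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& grad;
  const std::vector<double>& hess;
  int max_depth;
  double lambda, alpha, gamma, eta, min_child_weight;
  TreeNodes tree;

  Builder(const NumericMatrix& X_, const std::vector<double>& g_,
          const std::vector<double>& h_, int md, double lam, double al,
          double gam, double eta_, double mcw)
      : X(X_), grad(g_), hess(h_), max_depth(md), lambda(lam), alpha(al),
        gamma(gam), eta(eta_), min_child_weight(mcw) {}

  int make_leaf(double G, double H) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(-eta * thresh_l1(G, alpha) / (H + lambda));
    return (int)tree.feature.size() - 1;
  }

  // sorted[f] holds row indices of this node ordered by feature f
  int build(std::vector<std::vector<int> >& sorted, int depth) {
    const int d = X.ncol();
    double G = 0.0, H = 0.0;
    for (size_t k = 0; k < sorted[0].size(); ++k) {
      G += grad[sorted[0][k]];
      H += hess[sorted[0][k]];
    }
    double parent_score = thresh_l1(G, alpha);
    parent_score = parent_score * parent_score / (H + lambda);

    int best_f = -1;
    double best_gain = 0.0, best_thr = 0.0;
    size_t best_pos = 0;

    if (depth < max_depth && sorted[0].size() >= 2) {
      for (int f = 0; f < d; ++f) {
        const std::vector<int>& idx = sorted[f];
        double GL = 0.0, HL = 0.0;
        for (size_t k = 0; k + 1 < idx.size(); ++k) {
          GL += grad[idx[k]];
          HL += hess[idx[k]];
          double xv = X(idx[k], f), xn = X(idx[k + 1], f);
          if (xv == xn) continue;
          double HR = H - HL;
          if (HL < min_child_weight || HR < min_child_weight) continue;
          double GR = G - GL;
          double sl = thresh_l1(GL, alpha), sr = thresh_l1(GR, alpha);
          double gain = 0.5 * (sl * sl / (HL + lambda) +
                               sr * sr / (HR + lambda) - parent_score) - gamma;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (xv + xn);
            best_pos = k + 1;  // rows [0, best_pos) of idx go left
          }
        }
      }
    }

    if (best_f < 0) return make_leaf(G, H);

    // membership mask for the left child, then stable-partition every
    // feature's sorted list so children stay presorted
    std::vector<char> go_left_mask;
    {
      // mark rows by threshold on the chosen feature
      const std::vector<int>& idx = sorted[best_f];
      go_left_mask.assign(X.nrow(), 0);
      for (size_t k = 0; k < best_pos; ++k) go_left_mask[idx[k]] = 1;
    }
    const int dcols = (int)sorted.size();
    std::vector<std::vector<int> > left_sorted(dcols), right_sorted(dcols);
    for (int f = 0; f < dcols; ++f) {
      left_sorted[f].reserve(best_pos);
      right_sorted[f].reserve(sorted[f].size() - best_pos);
      for (size_t k = 0; k < sorted[f].size(); ++k) {
        int r = sorted[f][k];
        if (go_left_mask[r]) left_sorted[f].push_back(r);
        else right_sorted[f].push_back(r);
      }
      std::vector<int>().swap(sorted[f]);  // free as we descend
    }

    int node = (int)tree.feature.size();
    tree.feature.push_back(best_f);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    int l = build(left_sorted, depth + 1);
    int r = build(right_sorted, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

static double predict_tree(const NumericMatrix& tr, const NumericMatrix& X,
                           int row) {
  int node = 0;
  while ((int)tr(node, 0) >= 0) {
    int f = (int)tr(node, 0);
    node = (X(row, f) < tr(node, 1)) ? (int)tr(node, 2) : (int)tr(node, 3);
  }
  return tr(node, 4);
}

// [[Rcpp::export(name = ".xgb_train_cpp")]]
List xgb_train_cpp(NumericMatrix X, NumericVector y, int n_rounds,
                   double eta, int max_depth, double gamma, double lambda,
                   double alpha, double min_child_weight) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> margin(n, 0.0), grad(n), hess(n);

  // global presort per feature (reused every round via copy)
  std::vector<std::vector<int> > base_sorted(d);
  for (int f = 0; f < d; ++f) {
    base_sorted[f].resize(n);
    for (int i = 0; i < n; ++i) base_sorted[f][i] = i;
    const int ff = f;
    std::stable_sort(base_sorted[f].begin(), base_sorted[f].end(),
                     [&X, ff](int a, int b) { return X(a, ff) < X(b, ff); });
  }

  List trees(n_rounds);
  for (int round = 0; round < n_rounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = p - y[i];
      hess[i] = std::max(p * (1.0 - p), 1e-16);
    }
    Builder b(X, grad, hess, max_depth, lambda, alpha, gamma, eta,
              min_child_weight);
    std::vector<std::vector<int> > sorted = base_sorted;
    b.build(sorted, 0);

    int nn = (int)b.tree.feature.size();
    NumericMatrix tr(nn, 5);
    for (int k = 0; k < nn; ++k) {
      tr(k, 0) = b.tree.feature[k];
      tr(k, 1) = b.tree.threshold[k];
      tr(k, 2) = b.tree.left[k];
      tr(k, 3) = b.tree.right[k];
      tr(k, 4) = b.tree.value[k];
    }
    trees[round] = tr;
    for (int i = 0; i < n; ++i) margin[i] += predict_tree(tr, X, i);
  }
  return trees;
}

// [[Rcpp::export(name = ".xgb_predict_cpp")]]
NumericVector xgb_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector margin(n);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) margin[i] += predict_tree(tr, X, i);
  }
  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-margin[i]));
  return p;
}
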