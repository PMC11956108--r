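#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact-greedy regression trees for squared-error gradient boosting.
// For squared loss the per-observation hessian is 1, so xgboost's
// min_child_weight reduces to a minimum child sample count and the leaf
// weight is sum(residual) / (n_leaf + lambda).

namespace {

struct TreeNodes {
  std::vector<int> feat, left, right;
  std::vector<double> thr, val;
  int add() {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); val.push_back(0.0);
    return (int)feat.size() - 1;
  }
};

struct Split {
  int feat = -1;
  double thr = 0.0, gain = 0.0;
};

Split best_split(const NumericMatrix& X, const std::vector<double>& grad,
                 const std::vector<int>& rows, const std::vector<int>& cols,
                 double lambda, double min_child) {
  const int n = (int)rows.size();
  Split best;
  double G = 0.0;
  for (int i = 0; i < n; ++i) G += grad[rows[i]];
  const double parent = G * G / (n + lambda);

  std::vector<std::pair<double, double> > xg(n);  // (feature value, grad)
  for (size_t c = 0; c < cols.size(); ++c) {
    const int f = cols[c];
    for (int i = 0; i < n; ++i)
      xg[i] = std::make_pair(X(rows[i], f), grad[rows[i]]);
    std::sort(xg.begin(), xg.end());
    double GL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      GL += xg[i].second;
      if (xg[i].first == xg[i + 1].first) continue;
      const int nL = i + 1, nR = n - nL;
      if (nL < min_child || nR < min_child) continue;
      const double GR = G - GL;
      const double gain = GL * GL / (nL + lambda) + GR * GR / (nR + lambda) - parent;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feat = f;
        best.thr = 0.5 * (xg[i].first + xg[i + 1].first);
      }
    }
  }
  return best;
}

int grow(TreeNodes& t, const NumericMatrix& X, const std::vector<double>& grad,
         const std::vector<int>& rows, const std::vector<int>& cols,
         int depth, int max_depth, double lambda, double min_child, double eta) {
  const int id = t.add();
  double G = 0.0;
  for (size_t i = 0; i < rows.size(); ++i) G += grad[rows[i]];
  Split s;
  if (depth < max_depth && (double)rows.size() >= 2.0 * min_child)
    s = best_split(X, grad, rows, cols, lambda, min_child);
  if (s.feat < 0 || s.gain <= 1e-12) {
    t.val[id] = eta * G / ((double)rows.size() + lambda);
    return id;
  }
  std::vector<int> lr, rr;
  for (size_t i = 0; i < rows.size(); ++i) {
    if (X(rows[i], s.feat) < s.thr) lr.push_back(rows[i]);
    else rr.push_back(rows[i]);
  }
  const int l = grow(t, X, grad, lr, cols, depth + 1, max_depth, lambda, min_child, eta);
  const int r = grow(t, X, grad, rr, cols, depth + 1, max_depth, lambda, min_child, eta);
  t.feat[id] = s.feat; t.thr[id] = s.thr; t.left[id] = l; t.right[id] = r;
  return id;
}

double tree_value(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) < tree(node, 1)) ?
      (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

NumericMatrix pack(const TreeNodes& t) {
  NumericMatrix m((int)t.feat.size(), 5);
  for (size_t i = 0; i < t.feat.size(); ++i) {
    m(i, 0) = t.feat[i]; m(i, 1) = t.thr[i];
    m(i, 2) = t.left[i]; m(i, 3) = t.right[i]; m(i, 4) = t.val[i];
  }
  return m;
}

// partial Fisher-Yates draw of k items from 0..n-1 using R's RNG
std::vector<int> draw_k(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  std::sort(idx.begin(), idx.end());
  return idx;
}

}  // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                 double eta, double lambda, double subsample, double colsample,
                 double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  const double base = mean(y);
  std::vector<double> pred(n, base), grad(n);
  List trees(nrounds);
  const int nsub = std::max(2, (int)std::floor(subsample * n));
  const int psub = std::max(1, (int)std::floor(colsample * p));
  for (int k = 0; k < nrounds; ++k) {
    for (int i = 0; i < n; ++i) grad[i] = y[i] - pred[i];
    std::vector<int> rows = (nsub < n) ? draw_k(n, nsub) : draw_k(n, n);
    std::vector<int> cols = (psub < p) ? draw_k(p, psub) : draw_k(p, p);
    TreeNodes t;
    grow(t, X, grad, rows, cols, 0, max_depth, lambda, min_child_weight, eta);
    NumericMatrix tm = pack(t);
    trees[k] = tm;
    for (int i = 0; i < n; ++i) pred[i] += tree_value(tm, X, i);
  }
  return List::create(_["trees"] = trees, _["base_score"] = base,
                      _["fitted"] = NumericVector(pred.begin(), pred.end()));
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, double base_score, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int k = 0; k < trees.size(); ++k) {
    NumericMatrix tm = trees[k];
    for (int i = 0; i < n; ++i) out[i] += tree_value(tm, X, i);
  }
  return out;
}
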