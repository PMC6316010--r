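#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <utility>
#include <vector>
using namespace Rcpp;

// A compact binary-classification random forest (CART trees, Gini splits,
// bootstrap resampling, mtry feature subsampling) with out-of-bag
// permutation importance and impurity importance. The cohorts handled here
// are small (tens to low hundreds of samples), so trees are grown fully by
// recursive partitioning without depth pruning.
//
// All randomness comes from R's RNG (unif_rand), so results are
// reproducible with set.seed() at the R level.

namespace {

struct Tree {
  std::vector<int> var;      // split feature, -1 at leaves
  std::vector<double> split; // go left if x <= split
  std::vector<int> left, right;
  std::vector<double> leaf;  // class-1 fraction in the node
};

inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  const double p = static_cast<double>(n1) / n;
  return 2.0 * p * (1.0 - p);
}

inline int runif_int(int n) {
  int r = static_cast<int>(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

int grow_node(Tree &tr, const NumericMatrix &x, const IntegerVector &y,
              const std::vector<int> &idx, int mtry, int min_node,
              std::vector<double> &imp_gini, std::vector<int> &feat_buf) {
  const int id = static_cast<int>(tr.var.size());
  tr.var.push_back(-1);
  tr.split.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  const int n = static_cast<int>(idx.size());
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  tr.leaf.push_back(static_cast<double>(n1) / n);
  if (n < 2 * min_node || n1 == 0 || n1 == n) return id;

  const int p = x.ncol();
  // partial Fisher-Yates draw of mtry candidate features
  std::iota(feat_buf.begin(), feat_buf.end(), 0);
  for (int k = 0; k < mtry; ++k)
    std::swap(feat_buf[k], feat_buf[k + runif_int(p - k)]);

  const double parent = gini(n1, n);
  double best_gain = 1e-12, best_split = 0.0;
  int best_var = -1;
  std::vector<std::pair<double, int> > vals(n);
  for (int k = 0; k < mtry; ++k) {
    const int j = feat_buf[k];
    for (int i = 0; i < n; ++i) vals[i] = std::make_pair(x(idx[i], j), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl, r1 = n1 - l1;
      const double gain = parent -
                          (static_cast<double>(nl) / n) * gini(l1, nl) -
                          (static_cast<double>(nr) / n) * gini(r1, nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_var = j;
        best_split = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_var < 0) return id;

  std::vector<int> li, ri;
  li.reserve(n);
  ri.reserve(n);
  for (int i : idx)
    (x(i, best_var) <= best_split ? li : ri).push_back(i);
  if (li.empty() || ri.empty()) return id;
  tr.var[id] = best_var;
  tr.split[id] = best_split;
  imp_gini[best_var] += best_gain * n;
  const int l = grow_node(tr, x, y, li, mtry, min_node, imp_gini, feat_buf);
  tr.left[id] = l;
  const int r = grow_node(tr, x, y, ri, mtry, min_node, imp_gini, feat_buf);
  tr.right[id] = r;
  return id;
}

inline double predict_one(const Tree &tr, const NumericMatrix &x, int i,
                          int permute_var = -1, double permute_val = 0.0) {
  int id = 0;
  while (tr.var[id] >= 0) {
    const double v = (tr.var[id] == permute_var) ? permute_val : x(i, tr.var[id]);
    id = (v <= tr.split[id]) ? tr.left[id] : tr.right[id];
  }
  return tr.leaf[id];
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix x, IntegerVector y, int ntree, int mtry,
                  int min_node, bool permutation_importance) {
  const int n = x.nrow(), p = x.ncol();
  List trees(ntree);
  NumericVector imp_gini(p), imp_perm(p), imp_perm_sq(p);
  NumericVector oob_sum(n);
  IntegerVector oob_cnt(n);
  std::vector<int> idx;
  idx.reserve(n);
  std::vector<char> inbag(n);
  std::vector<int> feat_buf(p);
  for (int t = 0; t < ntree; ++t) {
    idx.clear();
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int r = runif_int(n);
      idx.push_back(r);
      inbag[r] = 1;
    }
    Tree tr;
    std::vector<double> ig(p, 0.0);
    grow_node(tr, x, y, idx, mtry, min_node, ig, feat_buf);
    for (int j = 0; j < p; ++j) imp_gini[j] += ig[j];

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    for (size_t k = 0; k < oob.size(); ++k) {
      const double pr = predict_one(tr, x, oob[k]);
      oob_sum[oob[k]] += pr;
      oob_cnt[oob[k]] += 1;
    }
    if (permutation_importance && !oob.empty()) {
      int base = 0;
      for (size_t k = 0; k < oob.size(); ++k)
        base += (predict_one(tr, x, oob[k]) > 0.5) == (y[oob[k]] == 1);
      std::vector<char> used(p, 0);
      for (size_t k = 0; k < tr.var.size(); ++k)
        if (tr.var[k] >= 0) used[tr.var[k]] = 1;
      std::vector<double> shuf(oob.size());
      for (int j = 0; j < p; ++j) {
        if (!used[j]) continue; // unused feature: exactly zero decrease
        for (size_t k = 0; k < oob.size(); ++k) shuf[k] = x(oob[k], j);
        for (int k = static_cast<int>(shuf.size()) - 1; k > 0; --k)
          std::swap(shuf[k], shuf[runif_int(k + 1)]);
        int corr = 0;
        for (size_t k = 0; k < oob.size(); ++k)
          corr += (predict_one(tr, x, oob[k], j, shuf[k]) > 0.5) ==
                  (y[oob[k]] == 1);
        const double d = static_cast<double>(base - corr) / oob.size();
        imp_perm[j] += d;
        imp_perm_sq[j] += d * d;
      }
    }
    trees[t] = List::create(
        _["var"] = wrap(tr.var), _["split"] = wrap(tr.split),
        _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
        _["leaf"] = wrap(tr.leaf));
  }
  // permutation importance as a Z-score: mean per-tree accuracy decrease
  // over its standard error (zero-variance features get Z = 0)
  NumericVector imp_z(p);
  for (int j = 0; j < p; ++j) {
    imp_gini[j] /= ntree;
    const double m = imp_perm[j] / ntree;
    const double v = imp_perm_sq[j] / ntree - m * m;
    imp_perm[j] = m;
    imp_z[j] = v > 0 ? m / std::sqrt(v / ntree) : 0.0;
  }
  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];
  return List::create(_["trees"] = trees, _["imp_impurity"] = imp_gini,
                      _["imp_permutation"] = imp_perm,
                      _["imp_zscore"] = imp_z,
                      _["oob_score"] = oob_pred);
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix x) {
  const int n = x.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    Tree tr;
    tr.var = as<std::vector<int> >(tl["var"]);
    tr.split = as<std::vector<double> >(tl["split"]);
    tr.left = as<std::vector<int> >(tl["left"]);
    tr.right = as<std::vector<int> >(tl["right"]);
    tr.leaf = as<std::vector<double> >(tl["leaf"]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(tr, x, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
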