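// Bagged regression forest for binary {0,1} predictors.
//
// Every predictor in this pipeline is a dominant marker score, so a split is
// always "band absent vs band present" and candidate evaluation is a single
// pass over the node. Trees are fully grown (leaf when the node is pure, has
// <= min_node samples, or no sampled candidate separates it). Out-of-bag
// samples give the honest MSE, and importance is the mean increase in OOB MSE
// when a predictor's OOB values are permuted (unscaled IncMSE).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat, left, right;  // feat = -1 for leaves
  std::vector<double> value;
};

inline int sample_int(int n) {  // 0..n-1 via R RNG
  int v = (int)(R::unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// X: column-major n x m binary matrix as raw pointer
void grow_tree(const int* X, int n, int m, const double* y,
               std::vector<int>& idx, int mtry, int min_node, Tree& tr,
               std::vector<int>& feat_pool, std::vector<bool>& used_feat,
               std::vector<int>& used_list) {
  struct Work { int node, lo, hi; };
  std::vector<Work> stack;
  tr.feat.clear(); tr.left.clear(); tr.right.clear(); tr.value.clear();
  tr.feat.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(0.0);
  stack.push_back({0, 0, (int)idx.size()});
  while (!stack.empty()) {
    Work w = stack.back(); stack.pop_back();
    const int nn = w.hi - w.lo;
    double sum = 0, sum2 = 0;
    for (int t = w.lo; t < w.hi; ++t) {
      const double yv = y[idx[t]];
      sum += yv; sum2 += yv * yv;
    }
    const double mean = sum / nn;
    tr.value[w.node] = mean;
    const double sse = sum2 - sum * mean;
    if (nn <= min_node || sse <= 1e-12) continue;
    // sample mtry distinct features (partial Fisher-Yates on a reusable pool)
    int best_f = -1;
    double best_gain = -1.0;
    for (int t = 0; t < mtry; ++t) {
      const int r = t + sample_int(m - t);
      std::swap(feat_pool[t], feat_pool[r]);
      const int f = feat_pool[t];
      const int* xc = X + (size_t)f * n;
      int n1 = 0; double s1 = 0;
      for (int u = w.lo; u < w.hi; ++u) {
        const int i = idx[u];
        if (xc[i]) { ++n1; s1 += y[i]; }
      }
      const int n0 = nn - n1;
      if (n0 == 0 || n1 == 0) continue;
      const double s0 = sum - s1;
      const double gain = s1 * s1 / n1 + s0 * s0 / n0;  // max => min child SSE
      if (gain > best_gain) { best_gain = gain; best_f = f; }
    }
    if (best_f < 0) continue;
    // partition idx[lo..hi): zeros first
    const int* xb = X + (size_t)best_f * n;
    int mid = w.lo;
    for (int u = w.lo; u < w.hi; ++u)
      if (!xb[idx[u]]) std::swap(idx[u], idx[mid++]);
    if (mid == w.lo || mid == w.hi) continue;
    const int L = tr.feat.size();
    tr.feat.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0);
    tr.feat.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0);
    tr.feat[w.node] = best_f; tr.left[w.node] = L; tr.right[w.node] = L + 1;
    if (!used_feat[best_f]) { used_feat[best_f] = true; used_list.push_back(best_f); }
    stack.push_back({L, w.lo, mid});
    stack.push_back({L + 1, mid, w.hi});
  }
}

inline double predict_one(const Tree& tr, const int* X, int n, int i) {
  int node = 0;
  int f;
  while ((f = tr.feat[node]) >= 0)
    node = X[(size_t)f * n + i] ? tr.right[node] : tr.left[node];
  return tr.value[node];
}

// prediction with feature pf's value taken from donor row
inline double predict_perm(const Tree& tr, const int* X, int n, int i,
                           int pf, int donor) {
  int node = 0;
  int f;
  while ((f = tr.feat[node]) >= 0) {
    const int x = X[(size_t)f * n + (f == pf ? donor : i)];
    node = x ? tr.right[node] : tr.left[node];
  }
  return tr.value[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_forest(IntegerMatrix X, NumericVector y, int ntree, int mtry,
               int min_node, bool importance) {
  const int n = X.nrow(), m = X.ncol();
  if (mtry > m) stop("mtry exceeds number of predictors");
  const int* Xp = INTEGER(X);
  const double* yp = REAL(y);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  NumericVector imp(m);
  std::vector<int> idx; idx.reserve(n);
  std::vector<bool> inbag(n);
  std::vector<int> feat_pool(m);
  for (int f = 0; f < m; ++f) feat_pool[f] = f;
  std::vector<bool> used_feat(m, false);
  std::vector<int> used_list;
  std::vector<int> oob; oob.reserve(n);
  std::vector<int> donor; donor.reserve(n);
  Tree tr;

  for (int b = 0; b < ntree; ++b) {
    idx.clear();
    std::fill(inbag.begin(), inbag.end(), false);
    for (int t = 0; t < n; ++t) {
      const int i = sample_int(n);
      idx.push_back(i);
      inbag[i] = true;
    }
    std::fill(used_feat.begin(), used_feat.end(), false);
    used_list.clear();
    grow_tree(Xp, n, m, yp, idx, mtry, min_node, tr, feat_pool, used_feat,
              used_list);
    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    double err = 0;
    for (size_t t = 0; t < oob.size(); ++t) {
      const double pr = predict_one(tr, Xp, n, oob[t]);
      const double e = yp[oob[t]] - pr;
      err += e * e;
      oob_sum[oob[t]] += pr;
      oob_cnt[oob[t]] += 1;
    }
    err /= oob.size();
    if (importance && !used_list.empty()) {
      for (int uf : used_list) {
        // independent random permutation of OOB rows per variable
        donor.assign(oob.begin(), oob.end());
        for (int t = (int)donor.size() - 1; t > 0; --t)
          std::swap(donor[t], donor[sample_int(t + 1)]);
        double errp = 0;
        for (size_t t = 0; t < oob.size(); ++t) {
          const double e = yp[oob[t]] -
            predict_perm(tr, Xp, n, oob[t], uf, donor[t]);
          errp += e * e;
        }
        errp /= oob.size();
        imp[uf] += errp - err;
      }
    }
  }
  NumericVector oob_pred(n);
  double mse = 0; int n_oob = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_cnt[i];
      const double e = yp[i] - oob_pred[i];
      mse += e * e;
      ++n_oob;
    } else {
      oob_pred[i] = NA_REAL;
    }
  }
  mse = n_oob ? mse / n_oob : NA_REAL;
  for (int f = 0; f < m; ++f) imp[f] /= ntree;
  return List::create(_["oob_pred"] = oob_pred, _["mse_oob"] = mse,
                      _["importance"] = imp);
}
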