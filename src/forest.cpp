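#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// CART regression trees with bootstrap aggregation. Randomness comes from
// R's RNG (RNGScope), so forests are reproducible from set.seed().

namespace {

struct TreeBuf {
  std::vector<int> split_var;     // 1-based predictor, 0 = leaf
  std::vector<double> split_val;  // x <= val goes left
  std::vector<int> left, right;   // 1-based node ids, 0 = none
  std::vector<double> pred;       // node mean of in-bag y
};

int new_node(TreeBuf &t) {
  t.split_var.push_back(0);
  t.split_val.push_back(NA_REAL);
  t.left.push_back(0);
  t.right.push_back(0);
  t.pred.push_back(NA_REAL);
  return (int)t.split_var.size() - 1;
}

// sample `m` distinct values from 0..p-1 (partial Fisher-Yates, R RNG)
void sample_vars(int p, int m, std::vector<int> &out, std::vector<int> &pool) {
  pool.resize(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

void grow(TreeBuf &t, int node, std::vector<int> &idx, int lo, int hi,
          const NumericMatrix &X, const NumericVector &y,
          int mtry, int min_node, std::vector<int> &vars,
          std::vector<int> &pool) {
  const int m = hi - lo;
  double sum = 0.0;
  for (int k = lo; k < hi; ++k) sum += y[idx[k]];
  t.pred[node] = sum / m;
  if (m <= min_node) return;  // at or below the terminal node size
  // constant response?
  bool cst = true;
  for (int k = lo + 1; k < hi && cst; ++k)
    if (y[idx[k]] != y[idx[lo]]) cst = false;
  if (cst) return;

  sample_vars(X.ncol(), mtry, vars, pool);
  double best_gain = 0.0, best_val = NA_REAL;
  int best_var = -1;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> best_left;
  for (int vi = 0; vi < (int)vars.size(); ++vi) {
    const int v = vars[vi];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, v) < X(b, v);
    });
    double sl = 0.0;
    const double tot2 = sum * sum / m;
    for (int k = 0; k < m - 1; ++k) {
      sl += y[ord[k]];
      if (X(ord[k], v) == X(ord[k + 1], v)) continue;  // not a boundary
      const int nl = k + 1, nr = m - nl;
      double gain = sl * sl / nl + (sum - sl) * (sum - sl) / nr - tot2;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_var = v;
        best_val = 0.5 * (X(ord[k], v) + X(ord[k + 1], v));
        best_left.assign(ord.begin(), ord.begin() + nl);
      }
    }
  }
  if (best_var < 0) return;  // no improving split among candidates

  // partition idx[lo..hi) into (<= best_val, > best_val) keeping stability
  std::vector<int> l, r;
  l.reserve(m);
  for (int k = lo; k < hi; ++k) {
    if (X(idx[k], best_var) <= best_val) l.push_back(idx[k]);
    else r.push_back(idx[k]);
  }
  t.split_var[node] = best_var + 1;
  t.split_val[node] = best_val;
  int nl = new_node(t), nr = new_node(t);
  t.left[node] = nl + 1;
  t.right[node] = nr + 1;
  std::copy(l.begin(), l.end(), idx.begin() + lo);
  std::copy(r.begin(), r.end(), idx.begin() + lo + (int)l.size());
  grow(t, nl, idx, lo, lo + (int)l.size(), X, y, mtry, min_node, vars, pool);
  grow(t, nr, idx, lo + (int)l.size(), hi, X, y, mtry, min_node, vars, pool);
}

double predict_one(const IntegerVector &sv, const NumericVector &sp,
                   const IntegerVector &lf, const IntegerVector &rg,
                   const NumericVector &pr, const NumericMatrix &X, int i) {
  int node = 0;
  while (sv[node] != 0) {
    node = (X(i, sv[node] - 1) <= sp[node] ? lf[node] : rg[node]) - 1;
  }
  return pr[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_grow_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                 int min_node) {
  const int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  std::vector<int> idx(n), vars, pool;
  for (int b = 0; b < ntree; ++b) {
    std::fill(idx.begin(), idx.end(), 0);
    IntegerMatrix::Column col = inbag(_, b);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
      col[j] += 1;
    }
    TreeBuf t;
    int root = new_node(t);
    grow(t, root, idx, 0, n, X, y, mtry, min_node, vars, pool);
    trees[b] = List::create(
        _["split_var"] = wrap(t.split_var), _["split_val"] = wrap(t.split_val),
        _["left"] = wrap(t.left), _["right"] = wrap(t.right),
        _["pred"] = wrap(t.pred));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector sv = tree["split_var"], lf = tree["left"], rg = tree["right"];
  NumericVector sp = tree["split_val"], pr = tree["pred"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(sv, sp, lf, rg, pr, X, i);
  return out;
}
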