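#include <Rcpp.h>
using namespace Rcpp;

// CART regression tree with variance-reduction splits. For 0/1 responses
// variance reduction is proportional to Gini impurity reduction, so one
// grower serves both the probability forest and the boosting machine.
// Feature subsampling (mtry) draws from R's RNG, so set.seed() on the R
// side makes tree growth reproducible.

struct Tree {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold;
  std::vector<int> left, right;  // child node ids, -1 for leaves
  std::vector<double> value;     // mean response in node
};

static int build(Tree& T, const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& rows, int lo, int hi, int depth,
                 int mtry, int max_depth, int min_node) {
  const int node = (int)T.feature.size();
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) { sum += y[rows[i]]; sum2 += y[rows[i]] * y[rows[i]]; }
  const double mean = sum / n;
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1); T.value.push_back(mean);

  const double sse = sum2 - sum * sum / n;
  if (depth >= max_depth || n < 2 * min_node || sse <= 1e-12) return node;

  // sample mtry distinct features via partial Fisher-Yates on R's RNG
  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int k = std::min(mtry, p);
  for (int j = 0; j < k; ++j) {
    int pick = j + (int)(unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(feats[j], feats[pick]);
  }

  int best_f = -1; double best_thr = 0.0, best_gain = 1e-12;
  std::vector<int> idx(n);
  for (int fi = 0; fi < k; ++fi) {
    const int f = feats[fi];
    for (int i = 0; i < n; ++i) idx[i] = rows[lo + i];
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0.0; int ln = 0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += y[idx[i]]; ++ln;
      if (X(idx[i], f) == X(idx[i + 1], f)) continue;
      if (ln < min_node || n - ln < min_node) continue;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / ln + rsum * rsum / (n - ln)
                          - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (X(idx[i], f) + X(idx[i + 1], f));
      }
    }
  }
  if (best_f < 0) return node;

  // partition rows[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[i], rows[mid++]);
  if (mid == lo || mid == hi) return node;  // degenerate (ties)

  T.feature[node] = best_f; T.threshold[node] = best_thr;
  const int l = build(T, X, y, rows, lo, mid, depth + 1, mtry, max_depth, min_node);
  T.left[node] = l;
  const int r = build(T, X, y, rows, mid, hi, depth + 1, mtry, max_depth, min_node);
  T.right[node] = r;
  return node;
}

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                   int mtry, int max_depth, int min_node) {
  Tree T;
  std::vector<int> rws(rows.begin(), rows.end());  // 0-based training rows
  GetRNGstate();
  build(T, X, y, rws, 0, (int)rws.size(), 0, mtry, max_depth, min_node);
  PutRNGstate();
  return List::create(_["feature"] = T.feature, _["threshold"] = T.threshold,
                      _["left"] = T.left, _["right"] = T.right,
                      _["value"] = T.value);
}

// [[Rcpp::export]]
IntegerVector tree_leaf_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = node;  // 0-based node id
  }
  return out;
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(List tree, NumericMatrix X) {
  NumericVector value = tree["value"];
  IntegerVector leaf = tree_leaf_cpp(tree, X);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = value[leaf[i]];
  return out;
}
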