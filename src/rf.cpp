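// Bagged classification-tree ensemble with out-of-bag permutation
// importance ("mean decrease accuracy"). Exhaustive Gini split search on
// mtry randomly drawn features per node, unpruned trees, bootstrap
// resampling per tree. Uses R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left when x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class, -1 for internal
};

inline int runif_int(int n) {           // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

double node_gini(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : cnt) { double p = (double)c / n; s += p * p; }
  return 1.0 - s;
}

int majority(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c) if (cnt[c] > cnt[best]) best = (int)c;
  return best;
}

struct Frame { int node; int lo; int hi; };

Tree grow_tree(const NumericMatrix &X, const IntegerVector &y, int nclass,
               std::vector<int> &idx, int mtry, int min_node) {
  const int p = X.ncol();
  Tree tr;
  std::vector<Frame> stack;
  tr.feature.push_back(-1); tr.threshold.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(-1);
  stack.push_back({0, 0, (int)idx.size()});

  std::vector<int> feats(p);
  std::vector<std::pair<double,int> > vals;
  std::vector<int> cl(nclass), cr(nclass), cnt(nclass);

  while (!stack.empty()) {
    Frame f = stack.back(); stack.pop_back();
    int n = f.hi - f.lo;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = f.lo; i < f.hi; ++i) cnt[y[idx[i]]]++;
    int maj = majority(cnt);
    bool pure = cnt[maj] == n;
    if (pure || n < 2 * min_node || n < 2) {
      tr.feature[f.node] = -1; tr.pred[f.node] = maj;
      continue;
    }
    // draw mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + runif_int(p - j)]);

    double parent = node_gini(cnt, n);
    double best_gain = 1e-12;            // require a real decrease
    int best_f = -1; double best_thr = 0.0;
    for (int jj = 0; jj < m; ++jj) {
      int j = feats[jj];
      vals.clear();
      for (int i = f.lo; i < f.hi; ++i)
        vals.push_back(std::make_pair(X(idx[i], j), y[idx[i]]));
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(cl.begin(), cl.end(), 0);
      cr = cnt;
      for (int i = 0; i < n - 1; ++i) {
        cl[vals[i].second]++; cr[vals[i].second]--;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double child = (nl * node_gini(cl, nl) + nr * node_gini(cr, nr)) / n;
        double gain = parent - child;
        if (gain > best_gain) {
          best_gain = gain; best_f = j;
          best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
        }
      }
    }
    if (best_f < 0) {                     // no admissible split among drawn features
      tr.feature[f.node] = -1; tr.pred[f.node] = maj;
      continue;
    }
    // partition idx[lo,hi) in place, preserving stability is not required
    int a = f.lo, b = f.hi - 1;
    while (a <= b) {
      if (X(idx[a], best_f) <= best_thr) ++a;
      else { std::swap(idx[a], idx[b]); --b; }
    }
    int mid = a;
    int nl_id = (int)tr.feature.size();
    tr.feature.push_back(-1); tr.threshold.push_back(0.0);
    tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(-1);
    int nr_id = (int)tr.feature.size();
    tr.feature.push_back(-1); tr.threshold.push_back(0.0);
    tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(-1);
    tr.feature[f.node] = best_f; tr.threshold[f.node] = best_thr;
    tr.left[f.node] = nl_id; tr.right[f.node] = nr_id;
    stack.push_back({nl_id, f.lo, mid});
    stack.push_back({nr_id, mid, f.hi});
  }
  return tr;
}

inline int tree_predict_row(const Tree &tr, const NumericMatrix &X, int row,
                            int swap_feature = -1, int swap_row = -1) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int j = tr.feature[node];
    int r = (j == swap_feature) ? swap_row : row;
    node = (X(r, j) <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

List tree_to_list(const Tree &tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.threshold),
                      _["left"] = wrap(tr.left),
                      _["right"] = wrap(tr.right),
                      _["pred"] = wrap(tr.pred));
}

Tree tree_from_list(const List &l) {
  Tree tr;
  tr.feature = as<std::vector<int> >(l["feature"]);
  tr.threshold = as<std::vector<double> >(l["threshold"]);
  tr.left = as<std::vector<int> >(l["left"]);
  tr.right = as<std::vector<int> >(l["right"]);
  tr.pred = as<std::vector<int> >(l["pred"]);
  return tr;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_node, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  IntegerMatrix oob_votes(n, nclass);
  NumericVector imp(p);
  List trees(ntree);
  std::vector<int> inbag, oob, perm;
  std::vector<char> seen(n);

  for (int t = 0; t < ntree; ++t) {
    inbag.clear(); std::fill(seen.begin(), seen.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = runif_int(n);
      inbag.push_back(k); seen[k] = 1;
    }
    oob.clear();
    for (int i = 0; i < n; ++i) if (!seen[i]) oob.push_back(i);
    Tree tr = grow_tree(X, y, nclass, inbag, mtry, min_node);
    trees[t] = tree_to_list(tr);
    if (oob.empty()) continue;
    int correct = 0;
    for (size_t i = 0; i < oob.size(); ++i) {
      int pr = tree_predict_row(tr, X, oob[i]);
      oob_votes(oob[i], pr)++;
      if (pr == y[oob[i]]) ++correct;
    }
    if (importance) {
      double acc0 = (double)correct / oob.size();
      perm = oob;
      for (int j = 0; j < p; ++j) {
        // fresh permutation of the OOB rows used for feature j only
        for (size_t i = 0; i + 1 < perm.size(); ++i)
          std::swap(perm[i], perm[i + runif_int((int)(perm.size() - i))]);
        int corr = 0;
        for (size_t i = 0; i < oob.size(); ++i)
          if (tree_predict_row(tr, X, oob[i], j, perm[i]) == y[oob[i]]) ++corr;
        imp[j] += acc0 - (double)corr / oob.size();
      }
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= ntree;
  return List::create(_["trees"] = trees, _["oob_votes"] = oob_votes,
                      _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X, int nclass) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) votes(i, tree_predict_row(tr, X, i))++;
  }
  return votes;
}
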