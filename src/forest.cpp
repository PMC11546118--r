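// Weighted random forest for two-class protein-abundance data.
//
// Trees are capacity-limited (max depth, weighted minimum leaf occupancy)
// and split on weighted Gini impurity.  Sample weights enter both the
// impurity and the leaf-occupancy counts; before each tree is grown the
// (bootstrapped) row weights are rescaled so their total equals the number
// of training rows, which keeps `min_leaf` on the familiar raw-count scale.
//
// Determinism: all randomness flows from one 64-bit seed through a
// splitmix64 stream (per-tree seeds), so a forest is bit-reproducible for a
// given seed regardless of R's RNG state.  Ties in the split search are
// broken toward the lowest feature index, then the lowest threshold.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

inline std::uint64_t splitmix64(std::uint64_t &state) {
  std::uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::uint64_t state;
  explicit Rng(std::uint64_t seed) : state(seed) {
    // warm up so nearby seeds decorrelate
    splitmix64(state);
    splitmix64(state);
  }
  std::uint64_t next() { return splitmix64(state); }
  // bounded draw; modulo bias is negligible for n << 2^64
  int below(int n) { return static_cast<int>(next() % static_cast<std::uint64_t>(n)); }
};

inline double gini2(double w0, double w1) {
  double t = w0 + w1;
  if (t <= 0.0) return 0.0;
  double p = w0 / t;
  return 2.0 * p * (1.0 - p);
}

struct Node {
  int left = 0, right = 0;   // 1-based row index into the node table; 0 = leaf
  int feature = 0;           // 1-based feature column; 0 = leaf
  double threshold = NA_REAL;
  double w0 = 0.0, w1 = 0.0; // weighted class totals at the node
  int nrows = 0;             // raw (bootstrap) row count
  int depth = 0;
  double impurity = 0.0;
};

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  const std::vector<double> &w; // rescaled weights
  int max_depth, mtry;
  double min_leaf;
  Rng &rng;
  std::vector<Node> nodes;
  std::vector<double> importance; // per-feature, unnormalized
  double w_root = 0.0;

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_,
              const std::vector<double> &w_, int max_depth_, double min_leaf_,
              int mtry_, Rng &rng_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), mtry(mtry_), min_leaf(min_leaf_),
        rng(rng_), importance(X_.ncol(), 0.0) {}

  int build(std::vector<int> &rows, int depth) {
    Node nd;
    nd.depth = depth;
    nd.nrows = static_cast<int>(rows.size());
    for (int i : rows) {
      if (y[i] == 0) nd.w0 += w[i]; else nd.w1 += w[i];
    }
    nd.impurity = gini2(nd.w0, nd.w1);
    double W = nd.w0 + nd.w1;
    if (depth == 0) w_root = W;
    int me = static_cast<int>(nodes.size());
    nodes.push_back(nd);

    if (depth >= max_depth || W < 2.0 * min_leaf || nd.impurity <= 0.0)
      return me;

    // sample mtry features without replacement, then visit in ascending
    // order so equal-gain ties resolve to the lowest feature index
    int p = X.ncol();
    int m = std::min(mtry, p);
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    for (int j = 0; j < m; ++j) {
      int k = j + rng.below(p - j);
      std::swap(feat[j], feat[k]);
    }
    feat.resize(m);
    std::sort(feat.begin(), feat.end());

    const double eps = 1e-12;
    double best_dec = 0.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int>> vals;
    vals.reserve(rows.size());

    for (int f : feat) {
      vals.clear();
      for (int i : rows) vals.emplace_back(X(i, f), i);
      std::sort(vals.begin(), vals.end());
      double wl0 = 0.0, wl1 = 0.0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        int i = vals[k].second;
        if (y[i] == 0) wl0 += w[i]; else wl1 += w[i];
        if (vals[k].first == vals[k + 1].first) continue;
        double wl = wl0 + wl1, wr = W - wl;
        if (wl < min_leaf || wr < min_leaf) continue;
        double wr0 = nd.w0 - wl0, wr1 = nd.w1 - wl1;
        double dec = W * nd.impurity - wl * gini2(wl0, wl1) - wr * gini2(wr0, wr1);
        if (dec <= eps) continue;
        double thr = 0.5 * (vals[k].first + vals[k + 1].first);
        // features and thresholds are visited in ascending order, so
        // keeping the first maximum realises the documented tie-break
        // (lowest feature index, then lowest threshold)
        if (best_f < 0 || dec > best_dec + eps) {
          best_dec = dec; best_thr = thr; best_f = f;
        }
      }
    }

    if (best_f < 0 || best_dec <= eps) return me;

    std::vector<int> left_rows, right_rows;
    left_rows.reserve(rows.size());
    right_rows.reserve(rows.size());
    for (int i : rows) {
      if (X(i, best_f) <= best_thr) left_rows.push_back(i);
      else right_rows.push_back(i);
    }
    // record the split before recursing
    nodes[me].feature = best_f + 1;
    nodes[me].threshold = best_thr;
    importance[best_f] += best_dec / w_root;

    int li = build(left_rows, depth + 1);
    nodes[me].left = li + 1;
    int ri = build(right_rows, depth + 1);
    nodes[me].right = ri + 1;
    return me;
  }
};

NumericMatrix pack_tree(const std::vector<Node> &nodes) {
  int n = static_cast<int>(nodes.size());
  NumericMatrix m(n, 9);
  for (int i = 0; i < n; ++i) {
    const Node &nd = nodes[i];
    m(i, 0) = nd.left;
    m(i, 1) = nd.right;
    m(i, 2) = nd.feature;
    m(i, 3) = nd.threshold;
    m(i, 4) = nd.w0;
    m(i, 5) = nd.w1;
    m(i, 6) = nd.nrows;
    m(i, 7) = nd.depth;
    m(i, 8) = nd.impurity;
  }
  colnames(m) = CharacterVector::create("left", "right", "feature", "threshold",
                                        "w0", "w1", "nrows", "depth", "impurity");
  return m;
}

} // namespace

// [[Rcpp::export(rng = false)]]
List cpp_build_forest(NumericMatrix X, IntegerVector y, NumericVector w,
                      int n_trees, int max_depth, double min_leaf, int mtry,
                      bool bootstrap, double seed) {
  int n = X.nrow();
  std::uint64_t seed_stream = static_cast<std::uint64_t>(seed);
  List trees(n_trees);
  NumericVector imp(X.ncol());

  for (int t = 0; t < n_trees; ++t) {
    std::uint64_t tree_seed = splitmix64(seed_stream);
    Rng rng(tree_seed);

    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = rng.below(n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    // rescale sampled weights so the tree's total weight equals n, and
    // fold duplicate bootstrap draws into one weighted row
    double tot = 0.0;
    for (int i : rows) tot += w[i];
    double scale = (tot > 0.0) ? n / tot : 0.0;
    std::vector<double> wt(n, 0.0);
    for (int i : rows) wt[i] += w[i] * scale;
    std::vector<int> urows;
    urows.reserve(n);
    for (int i = 0; i < n; ++i)
      if (wt[i] > 0.0) urows.push_back(i);

    TreeBuilder tb(X, y, wt, max_depth, min_leaf, mtry, rng);
    tb.build(urows, 0);
    trees[t] = pack_tree(tb.nodes);
    for (int j = 0; j < X.ncol(); ++j) imp[j] += tb.importance[j];
  }
  for (int j = 0; j < X.ncol(); ++j) imp[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  int n = X.nrow();
  int n_trees = trees.size();
  NumericVector prob(n, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr(node, 2) > 0) {
        int f = static_cast<int>(tr(node, 2)) - 1;
        node = (X(i, f) <= tr(node, 3)) ? static_cast<int>(tr(node, 0)) - 1
                                        : static_cast<int>(tr(node, 1)) - 1;
      }
      double w0 = tr(node, 4), w1 = tr(node, 5);
      double tot = w0 + w1;
      prob[i] += (tot > 0.0) ? w1 / tot : 0.5;
    }
  }
  for (int i = 0; i < n; ++i) prob[i] /= n_trees;
  return prob;
}

namespace {
double median_of(std::vector<double> &buf) {
  size_t n = buf.size();
  size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return 0.5 * (lo + hi);
}
} // namespace

// Bootstrap difference-in-medians statistics: each replicate resamples both
// groups independently with replacement and returns median(a*) - median(b*).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_boot_median_diff(NumericVector a, NumericVector b,
                                   int n_boot, double seed) {
  int na = a.size(), nb = b.size();
  Rng rng(static_cast<std::uint64_t>(seed));
  NumericVector out(n_boot);
  std::vector<double> bufa(na), bufb(nb);
  for (int r = 0; r < n_boot; ++r) {
    for (int i = 0; i < na; ++i) bufa[i] = a[rng.below(na)];
    for (int i = 0; i < nb; ++i) bufb[i] = b[rng.below(nb)];
    out[r] = median_of(bufa) - median_of(bufb);
  }
  return out;
}
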