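// Weighted-candidate CART forests with deterministic per-tree seeding.
//
// All randomness flows through a self-contained splitmix64 stream so that a
// forest is a pure function of (data, weights, params, tree seeds) and is
// bit-identical across platforms and worker partitions.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// splitmix64 (Steele, Lea & Flood 2014): full-period 64-bit mixer.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1) with 53 random bits
  double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  // uniform integer in {0, ..., n-1}; n small enough that the
  // floor(u * n) bias (< 2^-40 for n <= 2^13) is irrelevant here
  int unif_int(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

uint64_t hash_combine(uint64_t a, uint64_t b) {
  SplitMix s(a ^ (b + 0x9E3779B97F4A7C15ULL + (a << 6) + (a >> 2)));
  s.next();
  return s.next();
}

// Sequential weighted sampling without replacement: each draw picks index j
// with probability w[j] / sum(remaining w), then zeroes it out. Indices with
// zero weight can never be drawn.
std::vector<int> sample_candidates(const std::vector<double>& w, int mtry,
                                   SplitMix& rng) {
  const int p = static_cast<int>(w.size());
  std::vector<double> wr(w);
  double total = 0.0;
  int npos = 0;
  for (int j = 0; j < p; ++j) {
    total += wr[j];
    if (wr[j] > 0.0) ++npos;
  }
  const int k = std::min(mtry, npos);
  std::vector<int> out;
  out.reserve(k);
  for (int d = 0; d < k; ++d) {
    const double u = rng.unif() * total;
    double cum = 0.0;
    int pick = -1;
    for (int j = 0; j < p; ++j) {
      if (wr[j] <= 0.0) continue;
      cum += wr[j];
      if (u < cum) { pick = j; break; }
    }
    if (pick < 0) {  // u == total to rounding; take the last positive index
      for (int j = p - 1; j >= 0; --j)
        if (wr[j] > 0.0) { pick = j; break; }
    }
    out.push_back(pick);
    total -= wr[pick];
    wr[pick] = 0.0;
  }
  return out;
}

struct Split {
  int feature = -1;       // column index, -1 = no positive-decrease split
  double threshold = 0.0;
  double decrease = 0.0;
};

// Candidate thresholds are midpoints between consecutive distinct sorted
// values. Ties in decrease break to the lowest feature index, then the
// lowest threshold; candidates must be passed sorted ascending.
//
// Regression decrease is the drop in within-node sum of squared deviations,
//   SS(parent) - SS(left) - SS(right) = SL^2/nL + SR^2/nR - S^2/n,
// computed from cumulative sums in stable sorted order so an R oracle using
// cumsum() reproduces it bit for bit.
Split best_split_reg(const NumericMatrix& X, const NumericVector& y,
                     const std::vector<int>& idx,
                     const std::vector<int>& cand) {
  const int n = static_cast<int>(idx.size());
  Split best;
  std::vector<std::pair<double, double> > xy(n);
  for (int f : cand) {
    for (int i = 0; i < n; ++i)
      xy[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::stable_sort(xy.begin(), xy.end(),
                     [](const std::pair<double, double>& a,
                        const std::pair<double, double>& b) {
                       return a.first < b.first;
                     });
    double S = 0.0;
    for (int i = 0; i < n; ++i) S += xy[i].second;
    const double parent = S * S / n;
    double SL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      SL += xy[i].second;
      if (xy[i + 1].first <= xy[i].first) continue;  // not a distinct boundary
      const double mid = xy[i].first + (xy[i + 1].first - xy[i].first) / 2.0;
      if (mid <= xy[i].first || mid >= xy[i + 1].first) continue;  // fp underflow
      const int nl = i + 1, nr = n - nl;
      const double SR = S - SL;
      const double dec = SL * SL / nl + SR * SR / nr - parent;
      if (dec > best.decrease ||
          (dec == best.decrease && best.feature >= 0 &&
           (f < best.feature || (f == best.feature && mid < best.threshold)))) {
        if (dec > 0.0) {
          best.feature = f;
          best.threshold = mid;
          best.decrease = dec;
        }
      }
    }
  }
  return best;
}

double gini(const std::vector<int>& counts, int n) {
  double g = 1.0;
  for (int c : counts) {
    const double p = static_cast<double>(c) / n;
    g -= p * p;
  }
  return g;
}

// Classification decrease: Gini(parent) - nL/n * Gini(left) - nR/n * Gini(right)
Split best_split_cls(const NumericMatrix& X, const IntegerVector& y, int nclass,
                     const std::vector<int>& idx,
                     const std::vector<int>& cand) {
  const int n = static_cast<int>(idx.size());
  Split best;
  std::vector<std::pair<double, int> > xy(n);
  std::vector<int> total(nclass), left(nclass), right(nclass);
  for (int f : cand) {
    for (int i = 0; i < n; ++i)
      xy[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::stable_sort(xy.begin(), xy.end(),
                     [](const std::pair<double, int>& a,
                        const std::pair<double, int>& b) {
                       return a.first < b.first;
                     });
    std::fill(total.begin(), total.end(), 0);
    for (int i = 0; i < n; ++i) ++total[xy[i].second];
    const double gparent = gini(total, n);
    std::fill(left.begin(), left.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      ++left[xy[i].second];
      if (xy[i + 1].first <= xy[i].first) continue;
      const double mid = xy[i].first + (xy[i + 1].first - xy[i].first) / 2.0;
      if (mid <= xy[i].first || mid >= xy[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      for (int c = 0; c < nclass; ++c) right[c] = total[c] - left[c];
      const double dec = gparent -
        (static_cast<double>(nl) / n) * gini(left, nl) -
        (static_cast<double>(nr) / n) * gini(right, nr);
      if (dec > best.decrease ||
          (dec == best.decrease && best.feature >= 0 &&
           (f < best.feature || (f == best.feature && mid < best.threshold)))) {
        if (dec > 0.0) {
          best.feature = f;
          best.threshold = mid;
          best.decrease = dec;
        }
      }
    }
  }
  return best;
}

// Flat tree arrays; node 0 is the root. split_var == -1 marks a leaf.
struct Tree {
  std::vector<int> split_var;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> prediction;   // leaf value (class code for cls)
  std::vector<double> decrease;
  std::vector<int> n_node;

  int new_node(int n) {
    split_var.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    prediction.push_back(NA_REAL);
    decrease.push_back(0.0);
    n_node.push_back(n);
    return static_cast<int>(split_var.size()) - 1;
  }
};

class TreeGrower {
public:
  TreeGrower(const NumericMatrix& X, const NumericVector& yreg,
             const IntegerVector& ycls, bool regression, int nclass,
             const std::vector<double>& weights, int mtry, int min_node_size,
             SplitMix& rng)
      : X_(X), yreg_(yreg), ycls_(ycls), regression_(regression),
        nclass_(nclass), weights_(weights), mtry_(mtry),
        min_node_size_(min_node_size), rng_(rng) {}

  Tree grow(const std::vector<int>& root_idx) {
    tree_ = Tree();
    grow_node(root_idx);
    return tree_;
  }

private:
  const NumericMatrix& X_;
  const NumericVector& yreg_;
  const IntegerVector& ycls_;
  bool regression_;
  int nclass_;
  const std::vector<double>& weights_;
  int mtry_;
  int min_node_size_;
  SplitMix& rng_;
  Tree tree_;

  bool y_constant(const std::vector<int>& idx) const {
    if (regression_) {
      const double y0 = yreg_[idx[0]];
      for (int i : idx) if (yreg_[i] != y0) return false;
    } else {
      const int y0 = ycls_[idx[0]];
      for (int i : idx) if (ycls_[i] != y0) return false;
    }
    return true;
  }

  double leaf_value(const std::vector<int>& idx) const {
    if (regression_) {
      double s = 0.0;
      for (int i : idx) s += yreg_[i];
      return s / idx.size();
    }
    std::vector<int> counts(nclass_, 0);
    for (int i : idx) ++counts[ycls_[i]];
    int best = 0;
    for (int c = 1; c < nclass_; ++c)
      if (counts[c] > counts[best]) best = c;  // tie -> lowest class code
    return static_cast<double>(best);
  }

  int grow_node(const std::vector<int>& idx) {
    const int n = static_cast<int>(idx.size());
    const int id = tree_.new_node(n);
    if (n < 2 * min_node_size_ || n < 2 || y_constant(idx)) {
      tree_.prediction[id] = leaf_value(idx);
      return id;
    }
    std::vector<int> cand = sample_candidates(weights_, mtry_, rng_);
    std::sort(cand.begin(), cand.end());
    const Split sp = regression_
        ? best_split_reg(X_, yreg_, idx, cand)
        : best_split_cls(X_, ycls_, nclass_, idx, cand);
    if (sp.feature < 0) {
      tree_.prediction[id] = leaf_value(idx);
      return id;
    }
    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {
      if (X_(i, sp.feature) < sp.threshold) lidx.push_back(i);
      else ridx.push_back(i);
    }
    tree_.split_var[id] = sp.feature;
    tree_.threshold[id] = sp.threshold;
    tree_.decrease[id] = sp.decrease;
    tree_.left[id] = grow_node(lidx);
    tree_.right[id] = grow_node(ridx);
    return id;
  }
};

List tree_to_list(const Tree& t) {
  const int n = static_cast<int>(t.split_var.size());
  IntegerVector sv(n), lf(n), rt(n), nn(n);
  NumericVector th(n), pr(n), dc(n);
  for (int i = 0; i < n; ++i) {
    sv[i] = t.split_var[i] < 0 ? NA_INTEGER : t.split_var[i] + 1;  // 1-based
    lf[i] = t.left[i] < 0 ? NA_INTEGER : t.left[i] + 1;
    rt[i] = t.right[i] < 0 ? NA_INTEGER : t.right[i] + 1;
    th[i] = t.threshold[i];
    pr[i] = t.prediction[i];
    dc[i] = t.decrease[i];
    nn[i] = t.n_node[i];
  }
  return List::create(_["split_var"] = sv, _["threshold"] = th,
                      _["left"] = lf, _["right"] = rt,
                      _["prediction"] = pr, _["decrease"] = dc,
                      _["n_node"] = nn);
}

std::vector<int> bootstrap_indices(int m, bool bootstrap, SplitMix& rng) {
  std::vector<int> idx(m);
  if (bootstrap) {
    for (int i = 0; i < m; ++i) idx[i] = rng.unif_int(m);
    std::sort(idx.begin(), idx.end());  // sorted order keeps splits stable
  } else {
    for (int i = 0; i < m; ++i) idx[i] = i;
  }
  return idx;
}

double predict_one_tree(const List& tree, const NumericMatrix& X, int row) {
  const IntegerVector sv = tree["split_var"];
  const NumericVector th = tree["threshold"];
  const IntegerVector lf = tree["left"];
  const IntegerVector rt = tree["right"];
  const NumericVector pr = tree["prediction"];
  int node = 0;
  while (sv[node] != NA_INTEGER) {
    const int f = sv[node] - 1;
    node = (X(row, f) < th[node]) ? lf[node] - 1 : rt[node] - 1;
  }
  return pr[node];
}

}  // namespace

// [[Rcpp::export]]
double cpp_derive_seed(double seed, double stream, double index) {
  const uint64_t h = hash_combine(
      hash_combine(static_cast<uint64_t>(seed), static_cast<uint64_t>(stream)),
      static_cast<uint64_t>(index));
  return static_cast<double>(h >> 11);  // 53-bit, exactly representable
}

// [[Rcpp::export]]
IntegerVector cpp_sample_candidates(NumericVector weights, int mtry,
                                    double seed) {
  SplitMix rng(static_cast<uint64_t>(seed));
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<int> out = sample_candidates(w, mtry, rng);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, SEXP y, IntegerVector candidates,
                    bool regression, int nclass) {
  const int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  for (int& c : cand) --c;
  std::sort(cand.begin(), cand.end());
  Split sp;
  if (regression) {
    sp = best_split_reg(X, as<NumericVector>(y), idx, cand);
  } else {
    sp = best_split_cls(X, as<IntegerVector>(y), nclass, idx, cand);
  }
  if (sp.feature < 0) return List::create(_["leaf"] = true);
  return List::create(_["leaf"] = false, _["feature"] = sp.feature + 1,
                      _["threshold"] = sp.threshold,
                      _["decrease"] = sp.decrease);
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, SEXP y, bool regression, int nclass,
                     NumericVector weights, NumericVector seeds, int mtry,
                     int min_node_size, bool bootstrap) {
  const int m = X.nrow();
  const int p = X.ncol();
  const int n_trees = seeds.size();
  NumericVector yreg;
  IntegerVector ycls;
  if (regression) yreg = as<NumericVector>(y);
  else ycls = as<IntegerVector>(y);
  std::vector<double> w(weights.begin(), weights.end());

  List trees(n_trees);
  NumericVector importance(p);
  for (int t = 0; t < n_trees; ++t) {
    SplitMix rng(static_cast<uint64_t>(seeds[t]));
    std::vector<int> idx = bootstrap_indices(m, bootstrap, rng);
    TreeGrower grower(X, yreg, ycls, regression, nclass, w, mtry,
                      min_node_size, rng);
    Tree tr = grower.grow(idx);
    for (size_t i = 0; i < tr.split_var.size(); ++i)
      if (tr.split_var[i] >= 0) importance[tr.split_var[i]] += tr.decrease[i];
    trees[t] = tree_to_list(tr);
  }
  for (int j = 0; j < p; ++j) importance[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_trees(List trees, NumericMatrix X) {
  const int n_trees = trees.size();
  const int m = X.nrow();
  NumericMatrix out(m, n_trees);
  for (int t = 0; t < n_trees; ++t) {
    const List tree = trees[t];
    for (int i = 0; i < m; ++i) out(i, t) = predict_one_tree(tree, X, i);
  }
  return out;
}
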