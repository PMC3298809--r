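#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG for the importance permutations: splitmix64 keyed by
// (seed, tree, feature) so every permutation is reproducible independently
// of R's global RNG state and of evaluation order.
static inline uint64_t splitmix64(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t perm_key(int seed, int tree, int feature) {
  uint64_t s = (uint64_t)(uint32_t)seed;
  s = s * 6364136223846793005ULL + (uint64_t)(uint32_t)tree;
  s = s * 6364136223846793005ULL + (uint64_t)(uint32_t)feature;
  return s;
}

// Fisher-Yates shuffle of 0..m-1 under the keyed stream.
static void fy_perm(std::vector<int> &perm, int m, uint64_t key) {
  perm.resize(m);
  for (int i = 0; i < m; ++i) perm[i] = i;
  uint64_t state = key;
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(splitmix64(state) % (uint64_t)(i + 1));
    std::swap(perm[i], perm[j]);
  }
}

// [[Rcpp::export(name = ".perm_indices_cpp")]]
IntegerVector perm_indices_cpp(int seed, int tree, int feature, int m) {
  std::vector<int> perm;
  fy_perm(perm, m, perm_key(seed, tree, feature));
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = perm[i] + 1; // 1-based for R
  return out;
}

// Predict one regression tree (column `t` of the forest arrays) for row `row`
// of X. If `override_var` >= 0, that predictor's value is taken from
// `override_val` instead of X (used for the permuted column).
static inline double tree_predict_row(const IntegerMatrix &leftd,
                                      const IntegerMatrix &rightd,
                                      const IntegerMatrix &bestvar,
                                      const NumericMatrix &xsplit,
                                      const NumericMatrix &nodepred,
                                      const NumericMatrix &X,
                                      int t, int row,
                                      int override_var, double override_val) {
  int node = 0;
  for (;;) {
    int var = bestvar(node, t);
    if (var == 0) return nodepred(node, t); // terminal
    double xv = (var - 1 == override_var) ? override_val : X(row, var - 1);
    node = (xv <= xsplit(node, t)) ? (leftd(node, t) - 1) : (rightd(node, t) - 1);
  }
}

// [[Rcpp::export(name = ".rf_predict_tree_cpp")]]
NumericVector rf_predict_tree_cpp(IntegerMatrix leftd, IntegerMatrix rightd,
                                  IntegerMatrix bestvar, NumericMatrix xsplit,
                                  NumericMatrix nodepred, NumericMatrix X,
                                  int tree) {
  int n = X.nrow(), t = tree - 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_predict_row(leftd, rightd, bestvar, xsplit, nodepred, X,
                              t, i, -1, 0.0);
  return out;
}

// Out-of-bag permutation importance for a regression forest.
//
// For each tree t with OOB set O_t and each feature j:
//   d_tj = MSE_t(O_t, X with column j permuted within O_t) - MSE_t(O_t, X)
// Features never split on by tree t get d_tj = 0 exactly (the permutation
// cannot alter any prediction). Returns per-feature mean and SD of d_tj over
// trees with a non-empty OOB set.
// [[Rcpp::export(name = ".rf_oob_importance_cpp")]]
List rf_oob_importance_cpp(IntegerMatrix leftd, IntegerMatrix rightd,
                           IntegerMatrix bestvar, NumericMatrix xsplit,
                           NumericMatrix nodepred, IntegerVector ndbigtree,
                           IntegerMatrix inbag, NumericMatrix X,
                           NumericVector y, int perm_seed) {
  const int n = X.nrow(), p = X.ncol(), ntree = ndbigtree.size();
  std::vector<double> sum_d(p, 0.0), sumsq_d(p, 0.0);
  std::vector<int> oob, perm;
  std::vector<double> pred0, xperm;
  std::vector<char> used(p);
  int trees_used = 0;

  for (int t = 0; t < ntree; ++t) {
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int m = (int)oob.size();
    if (m == 0) continue;
    ++trees_used;

    // baseline OOB MSE
    const int mcast = m;
    pred0.assign(mcast, 0.0);
    double mse0 = 0.0;
    for (int k = 0; k < m; ++k) {
      pred0[k] = tree_predict_row(leftd, rightd, bestvar, xsplit, nodepred,
                                  X, t, oob[k], -1, 0.0);
      double e = y[oob[k]] - pred0[k];
      mse0 += e * e;
    }
    mse0 /= m;

    // predictors actually used by this tree
    std::fill(used.begin(), used.end(), 0);
    for (int node = 0; node < ndbigtree[t]; ++node) {
      int var = bestvar(node, t);
      if (var > 0) used[var - 1] = 1;
    }

    for (int j = 0; j < p; ++j) {
      if (!used[j]) continue; // d_tj = 0, already accounted (adds nothing)
      fy_perm(perm, m, perm_key(perm_seed, t + 1, j + 1));
      xperm.assign(m, 0.0);
      for (int k = 0; k < m; ++k) xperm[k] = X(oob[perm[k]], j);
      double mse1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double pr = tree_predict_row(leftd, rightd, bestvar, xsplit, nodepred,
                                     X, t, oob[k], j, xperm[k]);
        double e = y[oob[k]] - pr;
        mse1 += e * e;
      }
      mse1 /= m;
      double d = mse1 - mse0;
      sum_d[j] += d;
      sumsq_d[j] += d * d;
    }
  }

  NumericVector raw(p), sd(p);
  for (int j = 0; j < p; ++j) {
    if (trees_used == 0) { raw[j] = NA_REAL; sd[j] = NA_REAL; continue; }
    double mean = sum_d[j] / trees_used;
    raw[j] = mean;
    if (trees_used > 1) {
      double ss = sumsq_d[j] - trees_used * mean * mean;
      sd[j] = ss > 0 ? std::sqrt(ss / (trees_used - 1)) : 0.0;
    } else {
      sd[j] = 0.0;
    }
  }
  return List::create(_["raw"] = raw, _["sd"] = sd,
                      _["n_trees_used"] = trees_used);
}
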