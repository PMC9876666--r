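// Decision-tree and forest engine.
//
// Two classification growth modes mirror the two forest kinds used
// throughout the model: Gini-best splits among mtry random candidates
// ("random forest", kind B) and a completely random split — uniformly
// drawn feature and threshold — grown to pure leaves (kind A). A third
// mode grows multi-output SSE regression trees for the boosted
// correction step; their leaf values are assigned in R.
//
// Trees record per-node class counts, sample counts and Gini impurity so
// that importance scores, per-tree scoring/pruning and decision-path
// dumps can be computed without re-walking the training data.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuilder {
  std::vector<int> feature;     // split column (0-based), -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // node indices, -1 for leaf
  std::vector<int> nNode;
  std::vector<double> gini;
  std::vector<std::vector<double> > counts; // class counts (classification)

  int addNode(int n, double g, const std::vector<double>& cnt) {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    nNode.push_back(n);
    gini.push_back(g);
    counts.push_back(cnt);
    return static_cast<int>(feature.size()) - 1;
  }
};

double giniOf(const std::vector<double>& cnt, double n) {
  if (n <= 0.0) return 0.0;
  double s = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    double p = cnt[k] / n;
    s += p * p;
  }
  return 1.0 - s;
}

// Sample mtry distinct feature indices (partial Fisher-Yates).
void sampleFeatures(std::vector<int>& pool, int mtry, std::mt19937& rng) {
  int d = static_cast<int>(pool.size());
  for (int i = 0; i < mtry && i < d; ++i) {
    std::uniform_int_distribution<int> u(i, d - 1);
    std::swap(pool[i], pool[u(rng)]);
  }
}

struct ClassGrower {
  const NumericMatrix& X;
  const IntegerVector& y; // 0-based classes
  int K;
  int mode;               // 0 = gini-best, 1 = completely random
  int mtry;
  int maxDepth;
  int minNode;
  std::mt19937& rng;
  TreeBuilder tb;

  ClassGrower(const NumericMatrix& X_, const IntegerVector& y_, int K_,
              int mode_, int mtry_, int maxDepth_, int minNode_,
              std::mt19937& rng_)
      : X(X_), y(y_), K(K_), mode(mode_), mtry(mtry_), maxDepth(maxDepth_),
        minNode(minNode_), rng(rng_) {}

  int grow(std::vector<int>& idx, int depth) {
    int n = static_cast<int>(idx.size());
    std::vector<double> cnt(K, 0.0);
    for (int i = 0; i < n; ++i) cnt[y[idx[i]]] += 1.0;
    double g = giniOf(cnt, n);
    int node = tb.addNode(n, g, cnt);

    bool pure = false;
    for (int k = 0; k < K; ++k)
      if (cnt[k] == static_cast<double>(n)) pure = true;
    if (pure || depth >= maxDepth || n < 2 * minNode || n < 2) return node;

    int bestF = -1;
    double bestThr = 0.0;
    if (mode == 0) {
      bestGiniSplit(idx, cnt, g, bestF, bestThr);
    } else {
      randomSplit(idx, bestF, bestThr);
    }
    if (bestF < 0) return node;

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], bestF) <= bestThr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    if (li.empty() || ri.empty()) return node;

    tb.feature[node] = bestF;
    tb.threshold[node] = bestThr;
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    tb.left[node] = l;
    tb.right[node] = r;
    return node;
  }

  void bestGiniSplit(const std::vector<int>& idx,
                     const std::vector<double>& cnt, double gParent,
                     int& bestF, double& bestThr) {
    int n = static_cast<int>(idx.size());
    int d = X.ncol();
    std::vector<int> pool(d);
    for (int j = 0; j < d; ++j) pool[j] = j;
    sampleFeatures(pool, mtry, rng);

    double bestDec = 1e-12;
    std::vector<std::pair<double, int> > vals(n);
    std::vector<double> lc(K);
    for (int c = 0; c < mtry && c < d; ++c) {
      int f = pool[c];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(lc.begin(), lc.end(), 0.0);
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second] += 1.0;
        if (vals[i + 1].first <= vals[i].first) continue;
        double nL = i + 1.0, nR = n - nL;
        if (nL < minNode || nR < minNode) continue;
        double gL = giniOf(lc, nL);
        // right counts = cnt - lc
        double sR = 0.0;
        for (int k = 0; k < K; ++k) {
          double p = (cnt[k] - lc[k]) / nR;
          sR += p * p;
        }
        double gR = 1.0 - sR;
        double dec = gParent - (nL / n) * gL - (nR / n) * gR;
        if (dec > bestDec) {
          bestDec = dec;
          bestF = f;
          bestThr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
  }

  void randomSplit(const std::vector<int>& idx, int& bestF, double& bestThr) {
    int n = static_cast<int>(idx.size());
    int d = X.ncol();
    std::vector<int> pool(d);
    for (int j = 0; j < d; ++j) pool[j] = j;
    // full shuffle, then take the first feature that varies in the node
    for (int j = d - 1; j > 0; --j) {
      std::uniform_int_distribution<int> u(0, j);
      std::swap(pool[j], pool[u(rng)]);
    }
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (int c = 0; c < d; ++c) {
      int f = pool[c];
      double lo = X(idx[0], f), hi = lo;
      for (int i = 1; i < n; ++i) {
        double v = X(idx[i], f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi <= lo) continue;
      for (int attempt = 0; attempt < 8; ++attempt) {
        double thr = lo + unif(rng) * (hi - lo);
        if (thr >= hi) continue; // keep at least the max on the right
        int nL = 0;
        for (int i = 0; i < n; ++i)
          if (X(idx[i], f) <= thr) ++nL;
        if (nL > 0 && nL < n) {
          bestF = f;
          bestThr = thr;
          return;
        }
      }
    }
  }
};

struct RegGrower {
  const NumericMatrix& X;
  const NumericMatrix& Y; // n x K targets
  int K;
  int mtry;
  int maxDepth;
  int minNode;
  std::mt19937& rng;
  TreeBuilder tb;

  RegGrower(const NumericMatrix& X_, const NumericMatrix& Y_, int mtry_,
            int maxDepth_, int minNode_, std::mt19937& rng_)
      : X(X_), Y(Y_), K(Y_.ncol()), mtry(mtry_), maxDepth(maxDepth_),
        minNode(minNode_), rng(rng_) {}

  int grow(std::vector<int>& idx, int depth) {
    int n = static_cast<int>(idx.size());
    std::vector<double> sums(K, 0.0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) sums[k] += Y(idx[i], k);
    int node = tb.addNode(n, 0.0, sums);
    if (depth >= maxDepth || n < 2 * minNode || n < 2) return node;

    int bestF = -1;
    double bestThr = 0.0, bestGain = 1e-12;
    double parentScore = 0.0;
    for (int k = 0; k < K; ++k) parentScore += sums[k] * sums[k] / n;

    int d = X.ncol();
    std::vector<int> pool(d);
    for (int j = 0; j < d; ++j) pool[j] = j;
    sampleFeatures(pool, mtry, rng);

    std::vector<std::pair<double, int> > vals(n);
    std::vector<double> ls(K);
    for (int c = 0; c < mtry && c < d; ++c) {
      int f = pool[c];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), idx[i]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(ls.begin(), ls.end(), 0.0);
      for (int i = 0; i < n - 1; ++i) {
        for (int k = 0; k < K; ++k) ls[k] += Y(vals[i].second, k);
        if (vals[i + 1].first <= vals[i].first) continue;
        double nL = i + 1.0, nR = n - nL;
        if (nL < minNode || nR < minNode) continue;
        double score = 0.0;
        for (int k = 0; k < K; ++k) {
          double rs = sums[k] - ls[k];
          score += ls[k] * ls[k] / nL + rs * rs / nR;
        }
        double gain = score - parentScore; // SSE reduction
        if (gain > bestGain) {
          bestGain = gain;
          bestF = f;
          bestThr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (bestF < 0) return node;

    std::vector<int> li, ri;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], bestF) <= bestThr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    if (li.empty() || ri.empty()) return node;
    tb.feature[node] = bestF;
    tb.threshold[node] = bestThr;
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    tb.left[node] = l;
    tb.right[node] = r;
    return node;
  }
};

List packTree(const TreeBuilder& tb, int K, const std::vector<int>& inbag) {
  int nn = static_cast<int>(tb.feature.size());
  NumericMatrix cnt(nn, K);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < K; ++k) cnt(i, k) = tb.counts[i][k];
  IntegerVector ib(inbag.begin(), inbag.end());
  for (int i = 0; i < ib.size(); ++i) ib[i] += 1; // 1-based for R
  return List::create(
      _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["n"] = IntegerVector(tb.nNode.begin(), tb.nNode.end()),
      _["gini"] = NumericVector(tb.gini.begin(), tb.gini.end()),
      _["counts"] = cnt, _["inbag"] = ib);
}

int routeToLeaf(const IntegerVector& feature, const NumericVector& threshold,
                const IntegerVector& left, const IntegerVector& right,
                const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export(name = ".cppFitForest")]]
List cppFitForest(NumericMatrix X, IntegerVector y, int K, int nTrees,
                  int mode, int mtry, int maxDepth, int minNode,
                  bool bootstrap, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int n = X.nrow();
  List forest(nTrees);
  for (int t = 0; t < nTrees; ++t) {
    std::vector<int> idx;
    idx.reserve(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> u(0, n - 1);
      for (int i = 0; i < n; ++i) idx.push_back(u(rng));
    } else {
      for (int i = 0; i < n; ++i) idx.push_back(i);
    }
    std::vector<int> inbag(idx);
    ClassGrower g(X, y, K, mode, mtry, maxDepth, minNode, rng);
    std::vector<int> rootIdx(idx);
    g.grow(rootIdx, 0);
    forest[t] = packTree(g.tb, K, inbag);
  }
  return forest;
}

// [[Rcpp::export(name = ".cppFitRegTree")]]
List cppFitRegTree(NumericMatrix X, NumericMatrix Y, int mtry, int maxDepth,
                   int minNode, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  RegGrower g(X, Y, mtry, maxDepth, minNode, rng);
  g.grow(idx, 0);
  std::vector<int> inbag(idx.begin(), idx.end());
  return packTree(g.tb, Y.ncol(), inbag);
}

// [[Rcpp::export(name = ".cppPredictLeaf")]]
IntegerVector cppPredictLeaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = routeToLeaf(feature, threshold, left, right, X, i) + 1;
  return out;
}

// Mean of per-tree leaf class-frequency vectors over the trees of a forest.
// [[Rcpp::export(name = ".cppForestProba")]]
NumericMatrix cppForestProba(List forest, NumericMatrix X, int K) {
  int n = X.nrow();
  int nT = forest.size();
  NumericMatrix out(n, K);
  for (int t = 0; t < nT; ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    IntegerVector nn = tree["n"];
    NumericMatrix cnt = tree["counts"];
    for (int i = 0; i < n; ++i) {
      int leaf = routeToLeaf(feature, threshold, left, right, X, i);
      double tot = nn[leaf];
      for (int k = 0; k < K; ++k) out(i, k) += cnt(leaf, k) / tot;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) out(i, k) /= nT;
  return out;
}
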