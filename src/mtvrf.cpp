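// Multivariate random forest with a composite normalized Gini splitting
// rule: a candidate split is scored by sum_l w_l * dGini_l / Gini_l(parent),
// where Gini_l = 2 p_l (1 - p_l) at a node and dGini_l is the impurity
// decrease for label l. Labels pure at the parent contribute 0. Numeric
// splits at midpoints between sorted distinct values; categorical splits by
// prefix partitions of levels ordered by the weighted positive rate.
// All randomness goes through R's RNG so set.seed() controls determinism.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> split;    // threshold (numeric) or level bitmask (cat)
  std::vector<int> left, right; // child node ids, -1 at leaves
  std::vector<std::vector<double>> leaf; // per-label positive fractions
};

struct BestSplit {
  double score = 0.0;
  int feature = -1;
  bool isCat = false;
  double split = 0.0; // thr or mask
};

inline double gini2(double pos, double n) {
  double p = pos / n;
  return 2.0 * p * (1.0 - p);
}

// composite normalized Gini score of a candidate (left counts given)
inline double comp_score(const std::vector<double>& cntPos,
                         const std::vector<double>& leftPos,
                         double n, double nl,
                         const std::vector<double>& giniP,
                         const std::vector<double>& w) {
  double nr = n - nl;
  double s = 0.0;
  size_t L = cntPos.size();
  for (size_t l = 0; l < L; ++l) {
    if (giniP[l] <= 0.0) continue; // pure at parent
    double gl = gini2(leftPos[l], nl);
    double gr = gini2(cntPos[l] - leftPos[l], nr);
    double d = giniP[l] - (nl / n) * gl - (nr / n) * gr;
    s += w[l] * d / giniP[l];
  }
  return s;
}

class Grower {
public:
  Grower(const NumericMatrix& X, const IntegerMatrix& Y,
         const LogicalVector& isCat, const IntegerVector& nLevels,
         const std::vector<double>& w, int mtry, int minNodeSize)
    : X_(X), Y_(Y), isCat_(isCat), nLevels_(nLevels), w_(w),
      mtry_(mtry), minNodeSize_(minNodeSize),
      p_(X.ncol()), L_(Y.ncol()) {}

  TreeBuf grow(const std::vector<int>& rows) {
    buf_ = TreeBuf();
    build(rows);
    return buf_;
  }

private:
  const NumericMatrix& X_;
  const IntegerMatrix& Y_;
  const LogicalVector& isCat_;
  const IntegerVector& nLevels_;
  const std::vector<double>& w_;
  int mtry_, minNodeSize_, p_, L_;
  TreeBuf buf_;

  int newNode() {
    buf_.feature.push_back(-1);
    buf_.split.push_back(0.0);
    buf_.left.push_back(-1);
    buf_.right.push_back(-1);
    buf_.leaf.push_back(std::vector<double>());
    return (int)buf_.feature.size() - 1;
  }

  void makeLeaf(int id, const std::vector<double>& cntPos, double n) {
    std::vector<double> frac(L_);
    for (int l = 0; l < L_; ++l) frac[l] = cntPos[l] / n;
    buf_.leaf[id] = frac;
  }

  int build(const std::vector<int>& rows) {
    int id = newNode();
    double n = (double)rows.size();
    std::vector<double> cntPos(L_, 0.0);
    for (int r : rows)
      for (int l = 0; l < L_; ++l) cntPos[l] += Y_(r, l);

    std::vector<double> giniP(L_);
    bool anyImpure = false;
    for (int l = 0; l < L_; ++l) {
      giniP[l] = gini2(cntPos[l], n);
      if (giniP[l] > 0.0) anyImpure = true;
    }
    if ((int)rows.size() <= minNodeSize_ || !anyImpure) {
      makeLeaf(id, cntPos, n);
      return id;
    }

    // sample mtry features without replacement (partial Fisher-Yates, R RNG)
    std::vector<int> featIdx(p_);
    for (int j = 0; j < p_; ++j) featIdx[j] = j;
    int m = std::min(mtry_, p_);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p_ - j));
      if (k >= p_) k = p_ - 1;
      std::swap(featIdx[j], featIdx[k]);
    }

    BestSplit best;
    std::vector<double> leftPos(L_);
    for (int jj = 0; jj < m; ++jj) {
      int j = featIdx[jj];
      if (!isCat_[j]) {
        // numeric: sort node rows by feature value
        std::vector<std::pair<double, int>> v;
        v.reserve(rows.size());
        for (int r : rows) v.push_back({X_(r, j), r});
        std::stable_sort(v.begin(), v.end(),
          [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
            return a.first < b.first; });
        std::fill(leftPos.begin(), leftPos.end(), 0.0);
        for (size_t t = 0; t + 1 < v.size(); ++t) {
          int r = v[t].second;
          for (int l = 0; l < L_; ++l) leftPos[l] += Y_(r, l);
          if (v[t].first < v[t + 1].first) {
            double s = comp_score(cntPos, leftPos, n, (double)(t + 1),
                                  giniP, w_);
            if (s > best.score) {
              best.score = s; best.feature = j; best.isCat = false;
              best.split = 0.5 * (v[t].first + v[t + 1].first);
            }
          }
        }
      } else {
        int K = nLevels_[j];
        std::vector<double> levCnt(K, 0.0);
        std::vector<std::vector<double>> levPos(K, std::vector<double>(L_, 0.0));
        for (int r : rows) {
          int lv = (int)X_(r, j) - 1;
          if (lv < 0 || lv >= K) continue;
          levCnt[lv] += 1.0;
          for (int l = 0; l < L_; ++l) levPos[lv][l] += Y_(r, l);
        }
        std::vector<int> present;
        for (int k = 0; k < K; ++k) if (levCnt[k] > 0) present.push_back(k);
        if (present.size() < 2) continue;
        // order levels by weighted positive rate (greedy level partition)
        std::vector<double> rate(K, 0.0);
        for (int k : present) {
          double s = 0.0;
          for (int l = 0; l < L_; ++l) s += w_[l] * levPos[k][l] / levCnt[k];
          rate[k] = s;
        }
        std::stable_sort(present.begin(), present.end(),
          [&](int a, int b) {
            if (rate[a] != rate[b]) return rate[a] < rate[b];
            return a < b; });
        std::fill(leftPos.begin(), leftPos.end(), 0.0);
        double nl = 0.0;
        std::uint64_t mask = 0;
        for (size_t t = 0; t + 1 < present.size(); ++t) {
          int k = present[t];
          nl += levCnt[k];
          mask |= (std::uint64_t(1) << k);
          for (int l = 0; l < L_; ++l) leftPos[l] += levPos[k][l];
          double s = comp_score(cntPos, leftPos, n, nl, giniP, w_);
          if (s > best.score) {
            best.score = s; best.feature = j; best.isCat = true;
            best.split = (double)mask;
          }
        }
      }
    }

    if (best.feature < 0 || best.score <= 1e-12) {
      makeLeaf(id, cntPos, n);
      return id;
    }

    std::vector<int> rl, rr;
    std::uint64_t mask = (std::uint64_t)best.split;
    for (int r : rows) {
      bool goLeft;
      double x = X_(r, best.feature);
      if (best.isCat) {
        int lv = (int)x - 1;
        goLeft = (lv >= 0 && lv < 64 && ((mask >> lv) & 1));
      } else goLeft = (x <= best.split);
      if (goLeft) rl.push_back(r); else rr.push_back(r);
    }
    if (rl.empty() || rr.empty()) { // degenerate; should not happen
      makeLeaf(id, cntPos, n);
      return id;
    }
    buf_.feature[id] = best.feature;
    buf_.split[id] = best.split;
    int lid = build(rl);
    int rid = build(rr);
    buf_.left[id] = lid;
    buf_.right[id] = rid;
    return id;
  }
};

// route one row through a tree; feature `overrideF` (or -1) takes
// `overrideV` instead of the stored value
inline int route(const IntegerVector& feature, const NumericVector& split,
                 const IntegerVector& left, const IntegerVector& right,
                 const LogicalVector& isCat, const NumericMatrix& X,
                 int row, int overrideF, double overrideV) {
  int node = 0;
  while (feature[node] >= 0) {
    int j = feature[node];
    double x = (j == overrideF) ? overrideV : X(row, j);
    bool goLeft;
    if (isCat[j]) {
      int lv = (int)x - 1;
      std::uint64_t mask = (std::uint64_t)split[node];
      goLeft = (lv >= 0 && lv < 64 && ((mask >> lv) & 1));
    } else goLeft = (x <= split[node]);
    node = goLeft ? left[node] : right[node];
  }
  return node;
}

inline double hamming(const NumericMatrix& scoreSum,
                      const std::vector<double>& cnt,
                      const IntegerMatrix& Y, double threshold) {
  int n = scoreSum.nrow(), L = scoreSum.ncol();
  double bad = 0.0, cells = 0.0;
  for (int i = 0; i < n; ++i) {
    if (cnt[i] <= 0) continue;
    for (int l = 0; l < L; ++l) {
      int z = (scoreSum(i, l) / cnt[i] >= threshold) ? 1 : 0;
      if (z != Y(i, l)) bad += 1.0;
      cells += 1.0;
    }
  }
  return cells > 0 ? bad / cells : 0.0;
}

} // namespace

// [[Rcpp::export(name = ".mm_grow_forest")]]
List mm_grow_forest(NumericMatrix X, IntegerMatrix Y, LogicalVector isCat,
                    IntegerVector nLevels, NumericVector w, int nTrees,
                    int mtry, int minNodeSize) {
  RNGScope scope;
  int n = X.nrow();
  std::vector<double> wv(w.begin(), w.end());
  Grower grower(X, Y, isCat, nLevels, wv, mtry, minNodeSize);
  List trees(nTrees), oob(nTrees);
  std::vector<int> hit(n);
  for (int t = 0; t < nTrees; ++t) {
    std::fill(hit.begin(), hit.end(), 0);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      rows[i] = r;
      hit[r] = 1;
    }
    TreeBuf tb = grower.grow(rows);
    int nn = (int)tb.feature.size();
    NumericMatrix leaf(nn, Y.ncol());
    for (int i = 0; i < nn; ++i)
      if (!tb.leaf[i].empty())
        for (int l = 0; l < Y.ncol(); ++l) leaf(i, l) = tb.leaf[i][l];
    std::vector<int> oobRows;
    for (int i = 0; i < n; ++i) if (!hit[i]) oobRows.push_back(i + 1);
    trees[t] = List::create(
      Named("feature") = IntegerVector(tb.feature.begin(), tb.feature.end()),
      Named("split") = NumericVector(tb.split.begin(), tb.split.end()),
      Named("left") = IntegerVector(tb.left.begin(), tb.left.end()),
      Named("right") = IntegerVector(tb.right.begin(), tb.right.end()),
      Named("leaf") = leaf);
    oob[t] = IntegerVector(oobRows.begin(), oobRows.end());
  }
  return List::create(Named("trees") = trees, Named("oob") = oob);
}

// [[Rcpp::export(name = ".mm_forest_scores")]]
NumericMatrix mm_forest_scores(List trees, NumericMatrix X,
                               LogicalVector isCat, int nLabels) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, nLabels);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector split = tr["split"];
    NumericMatrix leaf = tr["leaf"];
    for (int i = 0; i < n; ++i) {
      int node = route(feature, split, left, right, isCat, X, i, -1, 0.0);
      for (int l = 0; l < nLabels; ++l) out(i, l) += leaf(node, l);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < nLabels; ++l) out(i, l) /= (double)T;
  return out;
}

// [[Rcpp::export(name = ".mm_oob_scores")]]
List mm_oob_scores(List trees, List oobList, NumericMatrix X,
                   LogicalVector isCat, int nLabels) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix sum(n, nLabels);
  NumericVector cnt(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector split = tr["split"];
    NumericMatrix leaf = tr["leaf"];
    IntegerVector o = oobList[t];
    for (int k = 0; k < o.size(); ++k) {
      int i = o[k] - 1;
      int node = route(feature, split, left, right, isCat, X, i, -1, 0.0);
      for (int l = 0; l < nLabels; ++l) sum(i, l) += leaf(node, l);
      cnt[i] += 1.0;
    }
  }
  return List::create(Named("sum") = sum, Named("count") = cnt);
}

// [[Rcpp::export(name = ".mm_perm_importance")]]
NumericVector mm_perm_importance(List trees, List oobList, NumericMatrix X,
                                 IntegerMatrix Y, LogicalVector isCat,
                                 int runs, double threshold) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol(), L = Y.ncol(), T = trees.size();

  // intact out-of-bag predictions and loss
  NumericMatrix baseSum(n, L);
  std::vector<double> baseCnt(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector split = tr["split"];
    NumericMatrix leaf = tr["leaf"];
    IntegerVector o = oobList[t];
    for (int k = 0; k < o.size(); ++k) {
      int i = o[k] - 1;
      int node = route(feature, split, left, right, isCat, X, i, -1, 0.0);
      for (int l = 0; l < L; ++l) baseSum(i, l) += leaf(node, l);
      baseCnt[i] += 1.0;
    }
  }
  double lossIntact = hamming(baseSum, baseCnt, Y, threshold);

  NumericVector imp(p);
  NumericMatrix sum(n, L);
  std::vector<double> cnt(n);
  std::vector<double> vals;
  for (int run = 0; run < runs; ++run) {
    for (int f = 0; f < p; ++f) {
      std::fill(sum.begin(), sum.end(), 0.0);
      std::fill(cnt.begin(), cnt.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        List tr = trees[t];
        IntegerVector feature = tr["feature"], left = tr["left"],
                      right = tr["right"];
        NumericVector split = tr["split"];
        NumericMatrix leaf = tr["leaf"];
        IntegerVector o = oobList[t];
        int no = o.size();
        if (no == 0) continue;
        // permute the feature's values among this tree's OOB rows
        vals.resize(no);
        for (int k = 0; k < no; ++k) vals[k] = X(o[k] - 1, f);
        for (int k = no - 1; k > 0; --k) {
          int j = (int)(unif_rand() * (k + 1));
          if (j > k) j = k;
          std::swap(vals[k], vals[j]);
        }
        for (int k = 0; k < no; ++k) {
          int i = o[k] - 1;
          int node = route(feature, split, left, right, isCat, X, i,
                           f, vals[k]);
          for (int l = 0; l < L; ++l) sum(i, l) += leaf(node, l);
          cnt[i] += 1.0;
        }
      }
      imp[f] += hamming(sum, cnt, Y, threshold) - lossIntact;
    }
  }
  for (int f = 0; f < p; ++f) imp[f] /= (double)runs;
  return imp;
}
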