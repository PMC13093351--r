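// Per-SNP regression forest with split-level importance accounting.
//
// Each tree is grown on a bootstrap sample with variance-reduction splits
// over mtry randomly chosen predictors.  Every accepted split accrues its
// impurity decrease (parent SS minus child SS) to the chosen predictor in
// the equal-width bin containing the split threshold; these binned
// importances are what the turnover functions are built from.  Out-of-bag
// samples are routed down each tree to leaf means for the OOB R^2.
// Randomness comes from R's RNG so set.seed() governs the forest.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct ForestCtx {
  const NumericMatrix& X;
  const NumericVector& y;
  int P, mtry, minLeaf, nbins;
  const NumericMatrix& edges;   // P x (nbins + 1)
  NumericMatrix& imp;           // nbins x P
  std::vector<double>& oobSum;
  std::vector<int>& oobCnt;

  ForestCtx(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
            int minLeaf_, int nbins_, const NumericMatrix& edges_,
            NumericMatrix& imp_, std::vector<double>& oobSum_,
            std::vector<int>& oobCnt_)
      : X(X_), y(y_), P(X_.ncol()), mtry(mtry_), minLeaf(minLeaf_),
        nbins(nbins_), edges(edges_), imp(imp_), oobSum(oobSum_),
        oobCnt(oobCnt_) {}

  int binOf(int p, double thr) const {
    double lo = edges(p, 0), hi = edges(p, nbins);
    if (hi <= lo) return 0;
    int b = (int)std::floor((thr - lo) / (hi - lo) * nbins);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    return b;
  }

  void leaf(const std::vector<int>& oob, double mean) {
    for (size_t i = 0; i < oob.size(); ++i) {
      oobSum[oob[i]] += mean;
      oobCnt[oob[i]] += 1;
    }
  }

  void build(std::vector<int>& in, std::vector<int>& oob) {
    const int n = (int)in.size();
    double S = 0.0, S2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = y[in[i]];
      S += v;
      S2 += v * v;
    }
    const double ssP = S2 - S * S / n;
    if (n < 2 * minLeaf || ssP <= 1e-12) {
      leaf(oob, S / n);
      return;
    }

    // mtry distinct predictors via partial Fisher-Yates
    std::vector<int> perm(P);
    for (int p = 0; p < P; ++p) perm[p] = p;
    int ncand = mtry < P ? mtry : P;
    for (int i = 0; i < ncand; ++i) {
      int j = i + (int)std::floor(unif_rand() * (P - i));
      if (j >= P) j = P - 1;
      std::swap(perm[i], perm[j]);
    }

    double bestGain = 1e-12;
    int bestP = -1;
    double bestThr = 0.0;
    std::vector<std::pair<double, double> > xy(n);
    for (int c = 0; c < ncand; ++c) {
      const int p = perm[c];
      for (int i = 0; i < n; ++i)
        xy[i] = std::make_pair(X(in[i], p), y[in[i]]);
      std::sort(xy.begin(), xy.end());
      double cumS = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        cumS += xy[i].second;
        const int nL = i + 1, nR = n - nL;
        if (nL < minLeaf) continue;
        if (nR < minLeaf) break;
        if (xy[i + 1].first - xy[i].first <= 1e-12) continue;
        const double SL = cumS, SR = S - cumS;
        const double gain = SL * SL / nL + SR * SR / nR - S * S / n;
        if (gain > bestGain) {
          bestGain = gain;
          bestP = p;
          bestThr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (bestP < 0) {
      leaf(oob, S / n);
      return;
    }
    imp(binOf(bestP, bestThr), bestP) += bestGain;

    std::vector<int> inL, inR, oobL, oobR;
    for (int i = 0; i < n; ++i) {
      if (X(in[i], bestP) <= bestThr) inL.push_back(in[i]);
      else inR.push_back(in[i]);
    }
    for (size_t i = 0; i < oob.size(); ++i) {
      if (X(oob[i], bestP) <= bestThr) oobL.push_back(oob[i]);
      else oobR.push_back(oob[i]);
    }
    build(inL, oobL);
    build(inR, oobR);
  }
};

}  // namespace

// [[Rcpp::export(name = ".snpForest")]]
List snpForest(NumericVector y, NumericMatrix X, int ntree, int mtry,
               int minLeaf, int nbins, NumericMatrix edges) {
  const int n = y.size();
  NumericMatrix imp(nbins, X.ncol());
  std::vector<double> oobSum(n, 0.0);
  std::vector<int> oobCnt(n, 0);
  ForestCtx ctx(X, y, mtry, minLeaf, nbins, edges, imp, oobSum, oobCnt);

  std::vector<int> in, oob;
  std::vector<char> inbag(n);
  for (int t = 0; t < ntree; ++t) {
    in.clear();
    oob.clear();
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      in.push_back(j);
      inbag[j] = 1;
    }
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    ctx.build(in, oob);
  }

  // OOB R^2 over samples with at least one OOB prediction
  double sy = 0.0;
  int m = 0;
  for (int i = 0; i < n; ++i)
    if (oobCnt[i] > 0) {
      sy += y[i];
      ++m;
    }
  double r2 = NA_REAL;
  if (m > 1) {
    const double ybar = sy / m;
    double ssRes = 0.0, ssTot = 0.0;
    for (int i = 0; i < n; ++i)
      if (oobCnt[i] > 0) {
        const double pred = oobSum[i] / oobCnt[i];
        ssRes += (y[i] - pred) * (y[i] - pred);
        ssTot += (y[i] - ybar) * (y[i] - ybar);
      }
    if (ssTot > 0) r2 = 1.0 - ssRes / ssTot;
  }
  return List::create(_["importance"] = imp, _["r2"] = r2);
}
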