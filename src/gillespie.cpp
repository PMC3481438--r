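// Gillespie direct-method stochastic simulation with residence-time
// weighted occupancy and moments. Uses R's RNG so set.seed() governs the
// trajectory: waiting times by inverse transform on unif_rand(), reaction
// selection by cumulative-sum search.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List gillespie_core(IntegerVector x0, IntegerMatrix nu, NumericVector rate,
                    List reactIdx, List reactCoef, double tEnd, double burnIn,
                    bool trackOccupancy, double maxEvents) {
  const int n = x0.size();
  const int M = rate.size();
  std::vector<std::vector<int>> ridx(M), rcoef(M), change(M);
  for (int m = 0; m < M; ++m) {
    IntegerVector iv = reactIdx[m], cv = reactCoef[m];
    ridx[m].assign(iv.begin(), iv.end());
    rcoef[m].assign(cv.begin(), cv.end());
    change[m].resize(n);
    for (int i = 0; i < n; ++i) change[m][i] = nu(i, m);
  }
  std::vector<long long> x(x0.begin(), x0.end());
  std::vector<double> a(M, 0.0);
  std::vector<double> s1(n, 0.0), s2(n, 0.0);
  std::map<std::vector<long long>, double> occ;
  double t = 0.0, tw = 0.0;
  double events = 0.0;
  RNGScope scope;

  auto propensity = [&](int m) {
    double v = rate[m];
    for (size_t q = 0; q < ridx[m].size(); ++q) {
      long long xv = x[ridx[m][q]];
      if (rcoef[m][q] == 1)
        v *= (double)xv;
      else
        v *= (double)xv * (double)(xv - 1) / 2.0;
    }
    return v > 0 ? v : 0.0;
  };

  auto accumulate = [&](double from, double to) {
    // overlap of (from, to] with (burnIn, tEnd]
    double lo = from > burnIn ? from : burnIn;
    double hi = to < tEnd ? to : tEnd;
    if (hi <= lo) return;
    double w = hi - lo;
    tw += w;
    for (int i = 0; i < n; ++i) {
      s1[i] += w * (double)x[i];
      s2[i] += w * (double)x[i] * (double)x[i];
    }
    if (trackOccupancy) occ[x] += w;
  };

  while (t < tEnd && events < maxEvents) {
    double a0 = 0.0;
    for (int m = 0; m < M; ++m) {
      a[m] = propensity(m);
      a0 += a[m];
    }
    if (a0 <= 0.0) {
      accumulate(t, tEnd);
      t = tEnd;
      break;
    }
    double u = unif_rand();
    while (u <= 0.0) u = unif_rand();
    double tau = -std::log(u) / a0;
    double tNext = t + tau;
    accumulate(t, tNext);
    if (tNext >= tEnd) {
      t = tEnd;
      break;
    }
    double target = unif_rand() * a0;
    double csum = 0.0;
    int mu = M - 1;
    for (int m = 0; m < M; ++m) {
      csum += a[m];
      if (target <= csum) {
        mu = m;
        break;
      }
    }
    for (int i = 0; i < n; ++i) x[i] += change[mu][i];
    t = tNext;
    events += 1.0;
  }

  NumericVector means(n), sds(n);
  for (int i = 0; i < n; ++i) {
    double mu1 = tw > 0 ? s1[i] / tw : (double)x[i];
    double mu2 = tw > 0 ? s2[i] / tw : (double)x[i] * (double)x[i];
    means[i] = mu1;
    double var = mu2 - mu1 * mu1;
    sds[i] = var > 0 ? std::sqrt(var) : 0.0;
  }
  IntegerMatrix states;
  NumericVector fractions;
  if (trackOccupancy) {
    states = IntegerMatrix(occ.size(), n);
    fractions = NumericVector(occ.size());
    int r = 0;
    for (auto& kv : occ) {
      for (int i = 0; i < n; ++i) states(r, i) = (int)kv.first[i];
      fractions[r] = tw > 0 ? kv.second / tw : 1.0;
      ++r;
    }
  }
  return List::create(_["means"] = means, _["sds"] = sds,
                      _["states"] = states, _["fractions"] = fractions,
                      _["events"] = events, _["weightedTime"] = tw);
}
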