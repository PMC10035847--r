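// Hot-path kernel for the reversible binary substitution model: pruning
// site likelihoods over a compressed pattern bank plus the (node state,
// 1-tip count) dynamic program for the observability-window probability,
// averaged over rate categories.  Mirrors the reference R implementation
// (.bin_site_loglik / .bin_count_dist_cat), which stays the documented
// algorithm; agreement is asserted in the test suite.
//
// No per-node rescaling: intended for the moderate taxon counts of
// gene-content matrices (conditional likelihoods stay far above the
// double underflow threshold).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = "bin_corrected_loglik_cpp")]]
double bin_corrected_loglik_cpp(IntegerMatrix X, NumericVector w, int n_chars,
                                IntegerVector order, IntegerVector parent,
                                IntegerVector pedge, int root,
                                NumericVector len, double pi1,
                                NumericVector rates,
                                int mmin, int mmax, bool condition) {
  const int n_tip = X.nrow();
  const int P = X.ncol();
  const int nnode = order.size();
  const int E = len.size();
  const int R = rates.size();
  const int root0 = root - 1;
  const double pi0 = 1.0 - pi1;
  const double mu = 1.0 / (2.0 * pi0 * pi1);
  const int K = n_tip + 1;

  std::vector<double> p00(E), p01(E), p10(E), p11(E);
  std::vector<double> part(2 * (size_t)nnode * P);
  std::vector<double> tab(2 * (size_t)nnode * K);
  std::vector<double> tmp(2 * (size_t)K);
  std::vector<int> cnt(nnode);
  std::vector<double> sitemix(P, 0.0);
  double pwin_mean = 0.0;

  for (int r = 0; r < R; ++r) {
    for (int e = 0; e < E; ++e) {
      double ef = std::exp(-mu * len[e] * rates[r]);
      p01[e] = pi1 * (1.0 - ef);
      p10[e] = pi0 * (1.0 - ef);
      p00[e] = 1.0 - p01[e];
      p11[e] = 1.0 - p10[e];
    }
    // initialise partials: tips to indicators (NA ambiguous), internals to 1
    for (int v = 0; v < nnode; ++v) {
      double *pv = &part[2 * (size_t)v * P];
      if (v < n_tip) {
        for (int p = 0; p < P; ++p) {
          int x = X(v, p);
          if (x == NA_INTEGER) { pv[p] = 1.0; pv[P + p] = 1.0; }
          else { pv[p] = (x == 0) ? 1.0 : 0.0; pv[P + p] = (x == 1) ? 1.0 : 0.0; }
        }
      } else {
        for (int p = 0; p < 2 * P; ++p) pv[p] = 1.0;
      }
      double *tv = &tab[2 * (size_t)v * K];
      for (int j = 0; j < 2 * K; ++j) tv[j] = 0.0;
      if (v < n_tip) { tv[0] = 1.0; tv[K + 1] = 1.0; cnt[v] = 1; }
      else { tv[0] = 1.0; tv[K] = 1.0; cnt[v] = 0; }
    }
    // postorder push into parents
    for (int i = 0; i < nnode; ++i) {
      int v = order[i] - 1;
      if (v == root0) continue;
      int u = parent[v] - 1;
      int e = pedge[v] - 1;
      const double *cv = &part[2 * (size_t)v * P];
      double *pu = &part[2 * (size_t)u * P];
      for (int p = 0; p < P; ++p) {
        double c0 = cv[p], c1 = cv[P + p];
        pu[p]     *= p00[e] * c0 + p01[e] * c1;
        pu[P + p] *= p10[e] * c0 + p11[e] * c1;
      }
      if (condition) {
        const double *tv = &tab[2 * (size_t)v * K];
        double *tu = &tab[2 * (size_t)u * K];
        int cv_n = cnt[v], cu_n = cnt[u];
        // A[s][j] = sum_s' P(s->s') tab_v[s'][j]
        for (int j = 0; j <= cv_n; ++j) {
          tmp[j]     = p00[e] * tv[j] + p01[e] * tv[K + j];
          tmp[K + j] = p10[e] * tv[j] + p11[e] * tv[K + j];
        }
        // in-place convolution of parent's table with A (descending j)
        for (int s = 0; s < 2; ++s) {
          double *ts = tu + s * K;
          const double *as = &tmp[s * (size_t)K];
          for (int j = cu_n + cv_n; j >= 0; --j) {
            double acc = 0.0;
            int lo = (j - cv_n > 0) ? j - cv_n : 0;
            int hi = (j < cu_n) ? j : cu_n;
            for (int j1 = lo; j1 <= hi; ++j1) acc += ts[j1] * as[j - j1];
            ts[j] = acc;
          }
        }
        cnt[u] = cu_n + cv_n;
      }
    }
    const double *pr = &part[2 * (size_t)root0 * P];
    for (int p = 0; p < P; ++p) {
      sitemix[p] += (pi0 * pr[p] + pi1 * pr[P + p]) / R;
    }
    if (condition) {
      const double *tr = &tab[2 * (size_t)root0 * K];
      double pwin = 0.0;
      for (int j = mmin; j <= mmax && j <= n_tip; ++j) {
        pwin += pi0 * tr[j] + pi1 * tr[K + j];
      }
      pwin_mean += pwin / R;
    }
  }
  double total = 0.0;
  for (int p = 0; p < P; ++p) {
    if (sitemix[p] <= 0.0) return R_NegInf;
    total += w[p] * std::log(sitemix[p]);
  }
  if (condition) {
    if (pwin_mean <= 0.0) return R_NegInf;
    total -= (double)n_chars * std::log(pwin_mean);
  }
  return total;
}
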