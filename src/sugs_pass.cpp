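#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One sequential greedy allocation pass of the SUGS algorithm.
//
// Observations are visited in `ordering` (1-based row indices of X). Each is
// allocated to the cluster maximising the posterior allocation probability
// with the DP concentration parameter marginalised over the discrete grid
// `beta` with current weights `phi`. Cluster/dimension posteriors are
// independent Normal-Gamma; only the columns in `maskIdx` (1-based) enter the
// likelihood. Ties in the argmax go to the lowest cluster label.
//
// Returns allocations in the original row order of X, final grid posterior,
// and per-cluster counts (clusters numbered in order of creation).
// [[Rcpp::export]]
List sugs_pass_cpp(NumericMatrix X, IntegerVector ordering, IntegerVector maskIdx,
                   double m0, double c0, double a0, double b0,
                   NumericVector beta, NumericVector phi0) {
  const int n = ordering.size();
  const int Don = maskIdx.size();
  const int L = beta.size();

  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<int> counts;                    // n_k per cluster
  std::vector< std::vector<double> > M, B;    // per-cluster location / rate, mask-on dims
  std::vector<double> sumlogb;                // per-cluster sum_j log b_j (cached)
  IntegerVector z(X.nrow(), NA_INTEGER);

  // lgamma(a + 1/2) - lgamma(a) for a = a0 + nk/2, cached over nk = 0..n
  std::vector<double> lgr(n + 1);
  for (int k = 0; k <= n; ++k) {
    double a = a0 + 0.5 * k;
    lgr[k] = std::lgamma(a + 0.5) - std::lgamma(a);
  }

  const double log_b0 = std::log(b0);
  std::vector<double> x(Don);

  for (int t = 0; t < n; ++t) {
    const int row = ordering[t] - 1;
    for (int j = 0; j < Don; ++j) x[j] = X(row, maskIdx[j] - 1);

    const int K = counts.size();
    int best = 0;
    if (K > 0) {
      // grid-marginalised CRP factors; t = number already allocated
      double s_exist = 0.0, s_new = 0.0;
      for (int l = 0; l < L; ++l) {
        double den = beta[l] + t;
        s_exist += phi[l] / den;
        s_new   += phi[l] * beta[l] / den;
      }
      double bestval = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        const int nk = counts[k];
        const double c = c0 + nk, a = a0 + 0.5 * nk;
        // Student-t predictive: df 2a, location m, squared scale b(c+1)/(ac)
        const double cdim = lgr[nk] - 0.5 * std::log(2.0 * M_PI * (c + 1.0) / c);
        const double fac = c / (2.0 * (c + 1.0));
        double lik = Don * cdim - 0.5 * sumlogb[k];
        const std::vector<double>& mk = M[k];
        const std::vector<double>& bk = B[k];
        for (int j = 0; j < Don; ++j) {
          const double zz = x[j] - mk[j];
          lik -= (a + 0.5) * std::log1p(zz * zz * fac / bk[j]);
        }
        const double u = std::log((double)nk * s_exist) + lik;
        if (u > bestval) { bestval = u; best = k; }
      }
      // new cluster: prior predictive
      {
        const double cdim = lgr[0] - 0.5 * std::log(2.0 * M_PI * (c0 + 1.0) / c0) - 0.5 * log_b0;
        const double fac = c0 / (2.0 * (c0 + 1.0) * b0);
        double lik = Don * cdim;
        for (int j = 0; j < Don; ++j) {
          const double zz = x[j] - m0;
          lik -= (a0 + 0.5) * std::log1p(zz * zz * fac);
        }
        const double u = std::log(s_new) + lik;
        if (u > bestval) best = K;
      }
      // grid posterior update: phi_l *= pi_{i z l}, normalised
      double tot = 0.0;
      if (best < K) {
        for (int l = 0; l < L; ++l) { phi[l] /= (beta[l] + t); tot += phi[l]; }
      } else {
        for (int l = 0; l < L; ++l) { phi[l] *= beta[l] / (beta[l] + t); tot += phi[l]; }
      }
      if (!(tot > 0.0)) stop("degenerate concentration-grid posterior (all weights zero)");
      for (int l = 0; l < L; ++l) phi[l] /= tot;
    }
    // else: first observation -> cluster 1; pi_{1,1,l} = 1 so phi stays at the prior

    if (best == (int)counts.size()) {
      counts.push_back(0);
      M.push_back(std::vector<double>(Don, m0));
      B.push_back(std::vector<double>(Don, b0));
      sumlogb.push_back(Don * log_b0);
    }
    z[row] = best + 1;

    // conjugate update of the chosen cluster with x
    {
      const double c = c0 + counts[best];
      std::vector<double>& mk = M[best];
      std::vector<double>& bk = B[best];
      double slb = sumlogb[best];
      for (int j = 0; j < Don; ++j) {
        const double d = x[j] - mk[j];
        mk[j] = (c * mk[j] + x[j]) / (c + 1.0);
        const double bnew = bk[j] + c * d * d / (2.0 * (c + 1.0));
        slb += std::log(bnew) - std::log(bk[j]);
        bk[j] = bnew;
      }
      sumlogb[best] = slb;
      counts[best] += 1;
    }
  }

  return List::create(_["z"] = z,
                      _["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["counts"] = IntegerVector(counts.begin(), counts.end()));
}
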