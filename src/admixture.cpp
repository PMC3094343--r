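// Gibbs sampler for the haploid admixture model with independent
// subpopulation band frequencies.
//
//   x_ij | z_ij = k            ~ Bernoulli(p_kj)
//   z_ij | q_i                 ~ Categorical(q_i)
//   p_kj                       ~ Beta(1, 1)
//   q_i                        ~ Dirichlet(1, ..., 1)
//
// Posterior-mean Q is accumulated after burn-in; label switching is handled
// by greedy matching of the frequency matrix p to the first retained sample.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_admixture(IntegerMatrix X, int K, int n_iter, int burnin) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix q(n, K), p(K, m), qsum(n, K), pref(K, m);
  IntegerMatrix z(n, m);
  std::vector<double> prob(K), gam(K);
  std::vector<int> c1(K), c0(K), perm(K);
  std::vector<double> ll_trace;
  ll_trace.reserve(n_iter);
  NumericMatrix nik(n, K);

  // init from priors
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = 0; k < K; ++k) { q(i, k) = R::rgamma(1.0, 1.0) + 1e-12; s += q(i, k); }
    for (int k = 0; k < K; ++k) q(i, k) /= s;
  }
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < m; ++j) p(k, j) = R::rbeta(1.0, 1.0);

  int n_samples = 0;
  for (int it = 0; it < n_iter; ++it) {
    std::fill(nik.begin(), nik.end(), 0.0);
    double ll = 0.0;
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) {
        const int x = X(i, j);
        double s = 0;
        for (int k = 0; k < K; ++k) {
          const double b = x ? p(k, j) : 1.0 - p(k, j);
          prob[k] = q(i, k) * b;
          s += prob[k];
        }
        ll += std::log(s > 1e-300 ? s : 1e-300);
        double u = R::unif_rand() * s, c = prob[0];
        int k = 0;
        while (u > c && k < K - 1) { ++k; c += prob[k]; }
        z(i, j) = k;
        nik(i, k) += 1.0;
      }
      std::fill(c1.begin(), c1.end(), 0);
      std::fill(c0.begin(), c0.end(), 0);
      for (int i = 0; i < n; ++i) {
        if (X(i, j)) ++c1[z(i, j)]; else ++c0[z(i, j)];
      }
      for (int k = 0; k < K; ++k)
        p(k, j) = R::rbeta(1.0 + c1[k], 1.0 + c0[k]);
    }
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < K; ++k) { gam[k] = R::rgamma(1.0 + nik(i, k), 1.0) + 1e-12; s += gam[k]; }
      for (int k = 0; k < K; ++k) q(i, k) = gam[k] / s;
    }
    ll_trace.push_back(ll);

    if (it >= burnin) {
      if (n_samples == 0) {
        for (int k = 0; k < K; ++k) {
          perm[k] = k;
          for (int j = 0; j < m; ++j) pref(k, j) = p(k, j);
        }
      } else {
        // greedy alignment: current label k -> reference label perm[k]
        std::vector<bool> used_cur(K, false), used_ref(K, false);
        for (int step = 0; step < K; ++step) {
          double best = R_PosInf;
          int bk = -1, bl = -1;
          for (int k = 0; k < K; ++k) {
            if (used_cur[k]) continue;
            for (int l = 0; l < K; ++l) {
              if (used_ref[l]) continue;
              double d = 0;
              for (int j = 0; j < m; ++j) {
                const double e = p(k, j) - pref(l, j);
                d += e * e;
              }
              if (d < best) { best = d; bk = k; bl = l; }
            }
          }
          perm[bk] = bl;
          used_cur[bk] = used_ref[bl] = true;
        }
      }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum(i, perm[k]) += q(i, k);
      ++n_samples;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) qsum(i, k) /= n_samples;
  return List::create(_["Q"] = qsum, _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}
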