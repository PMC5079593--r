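// Gibbs sampler for the admixture model: each of the two allele copies
// per individual x marker carries a latent ancestral origin; conjugate
// Beta / Dirichlet updates for population allele frequencies and
// individual ancestry proportions.  Uses R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int sweeps, int burnin,
                         double alpha, double lambda) {
  const int N = X.nrow(), L = X.ncol();
  NumericMatrix Pout(K, L), Qout(N, K);
  NumericVector lnL(sweeps - burnin);

  // locus-major copies of the state for cache-friendly access
  std::vector<double> P((size_t)K * L);     // P[l*K + k]
  std::vector<double> Q((size_t)N * K);     // Q[i*K + k]
  std::vector<double> Qsum((size_t)N * K, 0.0);
  std::vector<double> n1((size_t)K * L), n0((size_t)K * L);
  std::vector<double> m((size_t)N * K);
  std::vector<int> xcol(N);
  std::vector<double> w(K);

  for (size_t t = 0; t < P.size(); ++t) P[t] = R::rbeta(lambda, lambda);
  for (size_t t = 0; t < Q.size(); ++t) Q[t] = 1.0 / K;

  int kept = 0;
  for (int s = 0; s < sweeps; ++s) {
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);
    // (i) latent origin of every allele copy
    for (int l = 0; l < L; ++l) {
      const double *pl = &P[(size_t)l * K];
      double *n1l = &n1[(size_t)l * K], *n0l = &n0[(size_t)l * K];
      for (int i = 0; i < N; ++i) {
        int x = X(i, l);
        if (x == NA_INTEGER || x < 0) continue;
        const double *qi = &Q[(size_t)i * K];
        double *mi = &m[(size_t)i * K];
        for (int c = 0; c < 2; ++c) {
          int b = (c == 0) ? (x == 2) : (x >= 1);
          double tot = 0.0;
          if (b) for (int k = 0; k < K; ++k) { w[k] = qi[k] * pl[k]; tot += w[k]; }
          else   for (int k = 0; k < K; ++k) { w[k] = qi[k] * (1.0 - pl[k]); tot += w[k]; }
          int k = 0;
          if (tot > 0.0) {
            double u = unif_rand() * tot, acc = w[0];
            while (u > acc && k < K - 1) acc += w[++k];
          } else {
            k = (int)(unif_rand() * K);
            if (k >= K) k = K - 1;
          }
          if (b) n1l[k] += 1.0; else n0l[k] += 1.0;
          mi[k] += 1.0;
        }
      }
    }
    // (ii) population allele frequencies (Beta conjugate update)
    for (size_t t = 0; t < P.size(); ++t)
      P[t] = R::rbeta(lambda + n1[t], lambda + n0[t]);
    // (iii) ancestry proportions (Dirichlet conjugate update)
    for (int i = 0; i < N; ++i) {
      double *qi = &Q[(size_t)i * K];
      const double *mi = &m[(size_t)i * K];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { qi[k] = R::rgamma(alpha + mi[k], 1.0); tot += qi[k]; }
      for (int k = 0; k < K; ++k) qi[k] /= tot;
    }
    if (s >= burnin) {
      double ll = 0.0;
      for (int l = 0; l < L; ++l) {
        const double *pl = &P[(size_t)l * K];
        for (int i = 0; i < N; ++i) {
          int x = X(i, l);
          if (x == NA_INTEGER || x < 0) continue;
          const double *qi = &Q[(size_t)i * K];
          double f = 0.0;
          for (int k = 0; k < K; ++k) f += qi[k] * pl[k];
          if (f < 1e-12) f = 1e-12;
          if (f > 1.0 - 1e-12) f = 1.0 - 1e-12;
          if (x == 0) ll += 2.0 * std::log(1.0 - f);
          else if (x == 2) ll += 2.0 * std::log(f);
          else ll += std::log(2.0) + std::log(f) + std::log(1.0 - f);
        }
      }
      lnL[kept] = ll;
      for (size_t t = 0; t < Q.size(); ++t) Qsum[t] += Q[t];
      ++kept;
    }
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) {
      Qout(i, k) = Qsum[(size_t)i * K + k] / kept;
    }
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Pout(k, l) = P[(size_t)l * K + k];
  return List::create(_["Q"] = Qout, _["P"] = Pout, _["lnL"] = lnL);
}
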