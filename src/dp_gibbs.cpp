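// Collapsed Gibbs sampler for a Dirichlet-process binomial mixture over
// per-variant, per-sample CCFs.
//
// The emission per variant i and sample s is alt_is ~ Binomial(depth_is,
// phi_ks * c_is), where phi_ks is cluster k's CCF in sample s and c_is the
// precomputed VAF coefficient (purity * multiplicity / adjusted copy
// number). phi lives on a uniform grid over [0, 1]; the per-variant
// log-likelihood at every grid value is precomputed in R and passed in as a
// flat n x S x G array, so each sweep is table lookups plus categorical
// draws. All randomness goes through R's RNG, so set.seed() in R makes runs
// bit-for-bit reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static int sample_logweights(const std::vector<double> &lw) {
  double mx = lw[0];
  for (size_t j = 1; j < lw.size(); ++j) if (lw[j] > mx) mx = lw[j];
  double tot = 0.0;
  std::vector<double> w(lw.size());
  for (size_t j = 0; j < lw.size(); ++j) {
    w[j] = std::exp(lw[j] - mx);
    tot += w[j];
  }
  double u = unif_rand() * tot, cum = 0.0;
  for (size_t j = 0; j < lw.size(); ++j) {
    cum += w[j];
    if (u <= cum) return (int)j;
  }
  return (int)lw.size() - 1;
}

// [[Rcpp::export]]
List dp_gibbs_cpp(NumericVector L,      // n*S*G flat loglik table
                  NumericVector lognew, // n: log new-cluster predictive
                  int n, int S, int G,
                  int n_sweeps, int burn_in,
                  double alpha0, double a_alpha, double b_alpha) {
  auto LL = [&](int i, int s, int g) { return L[i + (R_xlen_t)n * (s + (R_xlen_t)S * g)]; };

  std::vector<int> z(n, 0);
  std::vector<int> counts;           // per-cluster sizes
  std::vector<std::vector<int>> phi; // per-cluster grid index per sample
  double alpha = alpha0;

  // start from one cluster with phi drawn from its conditional
  counts.push_back(n);
  {
    std::vector<int> p0(S);
    for (int s = 0; s < S; ++s) {
      std::vector<double> acc(G, 0.0);
      for (int i = 0; i < n; ++i)
        for (int g = 0; g < G; ++g) acc[g] += LL(i, s, g);
      p0[s] = sample_logweights(acc);
    }
    phi.push_back(p0);
  }

  NumericMatrix coclust(n, n);
  IntegerVector traceK(n_sweeps);
  NumericVector traceAlpha(n_sweeps);
  int n_saved = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    // 1. reassign each variant
    for (int i = 0; i < n; ++i) {
      int k = z[i];
      counts[k]--;
      if (counts[k] == 0) { // remove empty cluster (swap with last)
        int last = (int)counts.size() - 1;
        if (k != last) {
          counts[k] = counts[last];
          phi[k] = phi[last];
          for (int j = 0; j < n; ++j) if (z[j] == last) z[j] = k;
        }
        counts.pop_back();
        phi.pop_back();
      }
      int K = (int)counts.size();
      std::vector<double> lw(K + 1);
      for (int kk = 0; kk < K; ++kk) {
        double ll = 0.0;
        for (int s = 0; s < S; ++s) ll += LL(i, s, phi[kk][s]);
        lw[kk] = std::log((double)counts[kk]) + ll;
      }
      lw[K] = std::log(alpha) + lognew[i];
      int pick = sample_logweights(lw);
      if (pick == K) { // open a new cluster, draw its phi from this variant
        std::vector<int> pnew(S);
        for (int s = 0; s < S; ++s) {
          std::vector<double> acc(G);
          for (int g = 0; g < G; ++g) acc[g] = LL(i, s, g);
          pnew[s] = sample_logweights(acc);
        }
        phi.push_back(pnew);
        counts.push_back(1);
        z[i] = K;
      } else {
        counts[pick]++;
        z[i] = pick;
      }
    }

    // 2. resample phi per cluster and sample from its grid conditional
    int K = (int)counts.size();
    std::vector<std::vector<double>> acc((size_t)K * S,
                                         std::vector<double>(G, 0.0));
    for (int i = 0; i < n; ++i) {
      int k = z[i];
      for (int s = 0; s < S; ++s) {
        std::vector<double> &row = acc[(size_t)k * S + s];
        for (int g = 0; g < G; ++g) row[g] += LL(i, s, g);
      }
    }
    for (int k = 0; k < K; ++k)
      for (int s = 0; s < S; ++s)
        phi[k][s] = sample_logweights(acc[(size_t)k * S + s]);

    // 3. resample the concentration (Escobar & West 1995, Gamma(a,b) prior)
    {
      double eta = R::rbeta(alpha + 1.0, (double)n);
      double rate = b_alpha - std::log(eta);
      double ratio = (a_alpha + K - 1.0) / ((double)n * rate);
      double pi_k = ratio / (1.0 + ratio);
      if (unif_rand() < pi_k)
        alpha = R::rgamma(a_alpha + K, 1.0 / rate);
      else
        alpha = R::rgamma(a_alpha + K - 1.0, 1.0 / rate);
      if (alpha < 1e-8) alpha = 1e-8;
    }

    traceK[sweep] = K;
    traceAlpha[sweep] = alpha;

    // 4. accumulate posterior similarity after burn-in
    if (sweep >= burn_in) {
      n_saved++;
      std::vector<std::vector<int>> members(K);
      for (int i = 0; i < n; ++i) members[z[i]].push_back(i);
      for (int k = 0; k < K; ++k) {
        const std::vector<int> &m = members[k];
        for (size_t p = 0; p < m.size(); ++p)
          for (size_t q = p; q < m.size(); ++q) {
            coclust(m[p], m[q]) += 1.0;
            if (p != q) coclust(m[q], m[p]) += 1.0;
          }
      }
    }
  }

  return List::create(_["coclust"] = coclust, _["n_saved"] = n_saved,
                      _["trace_k"] = traceK, _["trace_alpha"] = traceAlpha,
                      _["last_z"] = IntegerVector(z.begin(), z.end()));
}
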