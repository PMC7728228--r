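#include <Rcpp.h>
using namespace Rcpp;

// Space-time single-site Metropolis sampler for a stationary dynamic Ising
// model: P(v) ~ exp( sum_{i,t} h[i] v[i][t]
//                    + 1/2 sum_{i,t,j,s} K[i][j][|t-s|] v[i][t] v[j][s] ),
// with K[i][j][tau] = 0 for tau > tau_max and K[i][i][0] = 0.
//
// h: length N.  K: N x N x (tau_max + 1), column-major.  v0: initial
// configuration, length N * T (column-major N x T).  One sweep = N * T
// randomly chosen single-site flip attempts.  After `burn_sweeps`, every
// `thin`-th sweep's configuration is retained; `n_keep` configurations are
// returned as an N x T x n_keep integer array.  Uses R's RNG stream.
// [[Rcpp::export]]
IntegerVector mcmc_spin_lattice(NumericVector h, NumericVector K,
                                int N, int T, int tau_max,
                                int n_keep, int burn_sweeps, int thin,
                                IntegerVector v0) {
  if ((int)h.size() != N) stop("h must have length N");
  if ((int)K.size() != N * N * (tau_max + 1)) stop("K has wrong size");
  if ((int)v0.size() != N * T) stop("v0 has wrong size");
  std::vector<int> v(v0.begin(), v0.end());
  IntegerVector out(Dimension(N, T, n_keep));
  const double *Kp = K.begin();
  const int NN = N * N;

  int total_sweeps = burn_sweeps + n_keep * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int flip = 0; flip < N * T; ++flip) {
      int i = (int)(unif_rand() * N);
      int t = (int)(unif_rand() * T);
      if (i >= N) i = N - 1;
      if (t >= T) t = T - 1;
      double b = h[i];
      int slo = t - tau_max; if (slo < 0) slo = 0;
      int shi = t + tau_max; if (shi > T - 1) shi = T - 1;
      for (int s = slo; s <= shi; ++s) {
        int tau = s > t ? s - t : t - s;
        const double *Kcol = Kp + (size_t)tau * NN + (size_t)i;
        const int *vcol = v.data() + (size_t)s * N;
        double acc = 0.0;
        for (int j = 0; j < N; ++j) acc += Kcol[(size_t)j * N] * vcol[j];
        b += acc;
      }
      // self term at (i, t) contributes K[i][i][0] = 0, nothing to subtract
      int vc = v[(size_t)t * N + i];
      double dE = -2.0 * vc * b;
      if (dE >= 0.0 || unif_rand() < std::exp(dE))
        v[(size_t)t * N + i] = -vc;
    }
    if (sweep >= burn_sweeps && (sweep - burn_sweeps + 1) % thin == 0) {
      if (kept < n_keep) {
        std::copy(v.begin(), v.end(), out.begin() + (size_t)kept * N * T);
        ++kept;
      }
    }
  }
  if (kept != n_keep) stop("internal error: retained configuration count");
  return out;
}
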