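// Admixture-model Bayesian clustering: collapsed data augmentation Gibbs
// sampler. Each diploid individual i carries two allele copies per locus;
// copy origins Z are sampled given cluster allele frequencies P and
// individual memberships Q; P and Q are then sampled from their Dirichlet
// full conditionals; the shared admixture concentration alpha is updated
// by random-walk Metropolis under a uniform prior on (0, alpha_max).
// Missing allele copies (code < 0) are skipped everywhere. Uses R's RNG,
// so results are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static void rdirichlet_inplace(std::vector<double> &alpha, double *out) {
  int k = alpha.size();
  double sum = 0.0;
  for (int i = 0; i < k; ++i) {
    out[i] = R::rgamma(alpha[i], 1.0);
    sum += out[i];
  }
  if (sum <= 0.0) { // numerically degenerate; fall back to uniform
    for (int i = 0; i < k; ++i) out[i] = 1.0 / k;
    return;
  }
  for (int i = 0; i < k; ++i) out[i] /= sum;
}

// log Dirichlet(alpha symmetric) density term summed over individuals:
// sum_i [ lgamma(K a) - K lgamma(a) + (a-1) sum_k log q_ik ]
static double alpha_logpost(double a, int K, int n, double sumlogq) {
  return n * (R::lgammafn(K * a) - K * R::lgammafn(a)) + (a - 1.0) * sumlogq;
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                     int burn_in, int n_reps, double lambda,
                     double alpha_init, double alpha_max,
                     double alpha_proposal_sd, int thin,
                     bool store_state) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");
  if (n < 1) stop("empty genotype matrix");

  // P[l] is a K x A_l matrix stored row-major as vector; Q is n x K
  std::vector< std::vector<double> > P(L);
  std::vector<int> A(L);
  int maxA = 0;
  for (int l = 0; l < L; ++l) {
    A[l] = n_alleles[l];
    if (A[l] < 1) stop("each locus needs >= 1 allele");
    if (A[l] > maxA) maxA = A[l];
    P[l].assign(K * A[l], 1.0 / A[l]);
  }
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  std::vector<int> Z(n * L * 2, 0);
  double alpha = (K == 1) ? 1.0 : alpha_init;

  std::vector<double> probs(K), dirpar(std::max(K, maxA));
  std::vector<double> clcount; // K x A_l allele counts per cluster
  std::vector<double> mcount(n * K); // copies of i assigned to k

  const int total = burn_in + n_reps;
  NumericVector lnl_trace(n_reps);
  NumericMatrix Qsum(n, K);
  int n_stored = 0;
  double alpha_sum = 0.0, alpha_min_seen = R_PosInf, alpha_max_seen = R_NegInf;
  List state_Q, state_P, state_lnl;
  if (store_state) {
    state_Q = List(0); state_P = List(0); state_lnl = List(0);
  }
  std::vector<double> qrow(K);

  for (int it = 0; it < total; ++it) {
    // --- sample Z given P, Q ---
    std::fill(mcount.begin(), mcount.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      std::vector<double> &Pl = P[l];
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            probs[k] = Q(i, k) * Pl[k * A[l] + a];
            s += probs[k];
          }
          int k = K - 1;
          if (s > 0.0) {
            double u = R::unif_rand() * s, acc = 0.0;
            for (int kk = 0; kk < K; ++kk) {
              acc += probs[kk];
              if (u <= acc) { k = kk; break; }
            }
          } else {
            k = (int)(R::unif_rand() * K); if (k == K) --k;
          }
          Z[(i * L + l) * 2 + c] = k;
          mcount[i * K + k] += 1.0;
        }
      }
    }
    // --- sample P given Z ---
    for (int l = 0; l < L; ++l) {
      clcount.assign(K * A[l], 0.0);
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          clcount[Z[(i * L + l) * 2 + c] * A[l] + a] += 1.0;
        }
      for (int k = 0; k < K; ++k) {
        std::vector<double> par(A[l]);
        for (int a = 0; a < A[l]; ++a) par[a] = lambda + clcount[k * A[l] + a];
        rdirichlet_inplace(par, &P[l][k * A[l]]);
      }
    }
    // --- sample Q given Z, alpha ---
    double sumlogq = 0.0;
    for (int i = 0; i < n; ++i) {
      std::vector<double> par(K);
      for (int k = 0; k < K; ++k) par[k] = alpha + mcount[i * K + k];
      rdirichlet_inplace(par, &qrow[0]);
      for (int k = 0; k < K; ++k) {
        double q = qrow[k];
        if (q < 1e-300) q = 1e-300;
        Q(i, k) = q;
        sumlogq += std::log(q);
      }
    }
    // --- alpha: random-walk Metropolis, uniform prior on (0, alpha_max) ---
    if (K > 1) {
      double prop = alpha + R::norm_rand() * alpha_proposal_sd;
      if (prop > 0.0 && prop < alpha_max) {
        double logr = alpha_logpost(prop, K, n, sumlogq) -
                      alpha_logpost(alpha, K, n, sumlogq);
        if (std::log(R::unif_rand()) < logr) alpha = prop;
      }
    }
    // --- likelihood of the data given current P, Q ---
    if (it >= burn_in) {
      double lnl = 0.0;
      for (int l = 0; l < L; ++l) {
        std::vector<double> &Pl = P[l];
        for (int i = 0; i < n; ++i)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a < 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += Q(i, k) * Pl[k * A[l] + a];
            lnl += std::log(std::max(s, 1e-300));
          }
      }
      int post = it - burn_in;
      lnl_trace[post] = lnl;
      alpha_sum += alpha;
      if (alpha < alpha_min_seen) alpha_min_seen = alpha;
      if (alpha > alpha_max_seen) alpha_max_seen = alpha;
      if (post % thin == 0) {
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
        ++n_stored;
        if (store_state) {
          state_Q.push_back(clone(Q));
          List pl(L);
          for (int l = 0; l < L; ++l) {
            NumericMatrix pm(K, A[l]);
            for (int k = 0; k < K; ++k)
              for (int a = 0; a < A[l]; ++a) pm(k, a) = P[l][k * A[l] + a];
            pl[l] = pm;
          }
          state_P.push_back(pl);
          state_lnl.push_back(lnl);
        }
      }
    }
  }

  // posterior mean Q, rows renormalized (each row of Qsum sums to n_stored)
  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qsum(i, k);
    if (s <= 0) s = 1.0;
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum(i, k) / s;
  }

  List out = List::create(
    _["q"] = Qmean, _["lnl_trace"] = lnl_trace,
    _["alpha_mean"] = alpha_sum / n_reps,
    _["alpha_range"] = NumericVector::create(alpha_min_seen, alpha_max_seen),
    _["n_stored"] = n_stored);
  if (store_state) {
    out["state_q"] = state_Q;
    out["state_p"] = state_P;
    out["state_lnl"] = state_lnl;
  }
  return out;
}
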