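// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// random-effects Hill concentration-response model.
//
// Observation model (vehicle-normalized response ratio, baseline 1):
//   y_ij = 1 + sgn * emax_i * f(c_ij; ec50_i, n) + eps,  eps ~ N(0, sig_err)
//   f(c) = c^n / (ec50^n + c^n) = logistic(n * (log c - log ec50))
// Donor level (non-centered, lognormal random effects):
//   log ec50_i = mu1 + sig1 * z1_i,  log emax_i = mu2 + sig2 * z2_i
// Priors (passed in; defaults documented on the R side):
//   mu1 ~ N(m1, s1);  mu2 ~ N(m2, s2) truncated at mu2 <= 0 (emax <= 1)
//   log n ~ N(mn, sn);  sig1, sig2 ~ half-N(0, sig_sd)
//   sig_err ~ half-N(0, sigerr_sd);  z ~ N(0, 1)
// Scale parameters are sampled on the log scale with the Jacobian included.
//
// One call runs one chain; the R wrapper manages chains, seeds (via R's RNG),
// convergence checks and posterior subsampling.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  const double *y;
  const double *logc; // -Inf encodes c = 0
  const int *donor;   // 0-based
  int n_obs, n_donors;
  double sgn;
  // prior hyperparameters
  double m1, s1, m2, s2, mn, sn, sig_sd, sigerr_sd;

  // log-likelihood of donor k's observations given current parameter vector
  double loglik_donor(const std::vector<double> &th, int k,
                      const std::vector<std::vector<int>> &idx) const {
    const double mu1 = th[0], mu2 = th[1], lnn = th[2];
    const double sig1 = std::exp(th[3]), sig2 = std::exp(th[4]);
    const double sige = std::exp(th[5]);
    const double lec50 = mu1 + sig1 * th[6 + k];
    const double emax = std::exp(mu2 + sig2 * th[6 + n_donors + k]);
    const double n = std::exp(lnn);
    if (!R_finite(emax) || !R_finite(lec50) || sige <= 0.0) return R_NegInf;
    double ll = 0.0;
    for (int t : idx[k]) {
      double f;
      if (logc[t] == R_NegInf) {
        f = 0.0;
      } else {
        double u = n * (logc[t] - lec50);
        f = 1.0 / (1.0 + std::exp(-u));
      }
      double m = 1.0 + sgn * emax * f;
      double r = (y[t] - m) / sige;
      ll += -0.5 * r * r - std::log(sige);
    }
    if (!R_finite(ll)) return R_NegInf;
    return ll;
  }

  double logprior(const std::vector<double> &th) const {
    const double mu1 = th[0], mu2 = th[1], lnn = th[2];
    const double ls1 = th[3], ls2 = th[4], lse = th[5];
    if (mu2 > 0.0) return R_NegInf; // emax (population median) <= 1
    double lp = 0.0;
    lp += -0.5 * std::pow((mu1 - m1) / s1, 2.0);
    lp += -0.5 * std::pow((mu2 - m2) / s2, 2.0);
    lp += -0.5 * std::pow((lnn - mn) / sn, 2.0);
    // half-normal on sigma, sampled as log(sigma): add Jacobian log|d sigma/d log sigma| = log sigma
    double sg1 = std::exp(ls1), sg2 = std::exp(ls2), sge = std::exp(lse);
    if (!R_finite(sg1) || !R_finite(sg2) || !R_finite(sge)) return R_NegInf;
    lp += -0.5 * std::pow(sg1 / sig_sd, 2.0) + ls1;
    lp += -0.5 * std::pow(sg2 / sig_sd, 2.0) + ls2;
    lp += -0.5 * std::pow(sge / sigerr_sd, 2.0) + lse;
    for (int k = 0; k < 2 * n_donors; ++k) lp += -0.5 * th[6 + k] * th[6 + k];
    return lp;
  }
};

} // namespace

// [[Rcpp::export]]
List hill_mcmc_chain(NumericVector y, NumericVector logc, IntegerVector donor,
                     int n_donors, double sgn, int n_iter, NumericVector prior,
                     NumericVector init) {
  const int n_obs = y.size();
  Model mod;
  mod.y = REAL(y);
  mod.logc = REAL(logc);
  mod.donor = INTEGER(donor);
  mod.n_obs = n_obs;
  mod.n_donors = n_donors;
  mod.sgn = sgn;
  mod.m1 = prior[0]; mod.s1 = prior[1];
  mod.m2 = prior[2]; mod.s2 = prior[3];
  mod.mn = prior[4]; mod.sn = prior[5];
  mod.sig_sd = prior[6]; mod.sigerr_sd = prior[7];

  std::vector<std::vector<int>> idx(n_donors);
  for (int t = 0; t < n_obs; ++t) idx[donor[t]].push_back(t);

  const int P = 6 + 2 * n_donors;
  if (init.size() != P) stop("init length must be 6 + 2 * n_donors");
  std::vector<double> th(init.begin(), init.end());

  std::vector<double> ll_donor(n_donors);
  double ll = 0.0;
  for (int k = 0; k < n_donors; ++k) {
    ll_donor[k] = mod.loglik_donor(th, k, idx);
    ll += ll_donor[k];
  }
  double lp = mod.logprior(th);
  if (!R_finite(ll + lp)) stop("non-finite log posterior at initial values");

  std::vector<double> lstep(P, std::log(0.2));
  std::vector<int> acc(P, 0), tries(P, 0);
  const int warmup = n_iter / 2;
  const int batch = 25;
  const int n_keep = n_iter - warmup;
  NumericMatrix draws(n_keep, P);
  int n_batches_done = 0;

  std::vector<double> prop_ll_donor(n_donors);

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < P; ++j) {
      const double old = th[j];
      th[j] = old + std::exp(lstep[j]) * norm_rand();
      double new_lp = mod.logprior(th);
      double delta;
      if (new_lp == R_NegInf) {
        delta = R_NegInf;
      } else if (j < 6) {
        // global parameter: full likelihood changes
        double new_ll = 0.0;
        for (int k = 0; k < n_donors; ++k) {
          prop_ll_donor[k] = mod.loglik_donor(th, k, idx);
          new_ll += prop_ll_donor[k];
        }
        delta = (new_ll + new_lp) - (ll + lp);
        if (delta > 0 || std::log(unif_rand()) < delta) {
          ll = new_ll; lp = new_lp;
          ll_donor = prop_ll_donor;
          ++acc[j]; ++tries[j];
          continue;
        }
        th[j] = old; ++tries[j];
        continue;
      } else {
        // donor-level z: only that donor's slice changes
        int k = (j - 6) % n_donors;
        double new_llk = mod.loglik_donor(th, k, idx);
        delta = (new_llk - ll_donor[k]) + (new_lp - lp);
        if (delta > 0 || std::log(unif_rand()) < delta) {
          ll += new_llk - ll_donor[k];
          ll_donor[k] = new_llk;
          lp = new_lp;
          ++acc[j]; ++tries[j];
          continue;
        }
        th[j] = old; ++tries[j];
        continue;
      }
      th[j] = old; ++tries[j];
    }

    // step-size adaptation during warmup only (target ~0.44 univariate)
    if (it < warmup && (it + 1) % batch == 0) {
      ++n_batches_done;
      double gain = std::min(0.25, 1.0 / std::sqrt((double)n_batches_done));
      for (int j = 0; j < P; ++j) {
        double rate = tries[j] > 0 ? (double)acc[j] / tries[j] : 0.0;
        lstep[j] += (rate > 0.44 ? gain : -gain);
        acc[j] = 0; tries[j] = 0;
      }
    }

    if (it >= warmup) {
      for (int j = 0; j < P; ++j) draws(it - warmup, j) = th[j];
    }
  }

  return List::create(_["draws"] = draws);
}
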