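// Metropolis-within-Gibbs sampler for the joint immune-response /
// toxicity / ordinal-efficacy model. The likelihood depends on the data
// only through per-cell sufficient statistics (counts, z-sums per
// (dose, schedule, subgroup) cell), so a full log-posterior evaluation is
// O(J*K) regardless of the number of patients; every scalar update simply
// re-evaluates the full log posterior.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Variant { PROPOSED = 0, DOSE_ADJ = 1, ALT1 = 2, ALT2 = 3 };
enum Kind { RW = 0, LOGRW = 1, GIBBS_SIGMA = 2 };

struct Model {
  int J, K, variant;
  bool use_lik;                      // false = prior-only sampling hook
  // sufficient statistics
  std::vector<double> n_cell, sz, sz2, y0, y1, y2;   // length J*K*2
  std::vector<double> n_jk, x_jk;                    // length J*K
  std::vector<double> d;                             // scaled doses
  // hyperparameters
  std::vector<double> zeta0k;
  double tau2, se0, se1;             // variances
  // prior constants
  double a_shape, a_rate, d_shape, d_rate, ig_a, ig_b, nu_sd,
      b1_scale, g_scale, g2_scale, b0_mean, b0_sd, lam_upper, mu_scale,
      alt2_int_sd;
  // parameter layout
  int i_alpha, i_delta, i_nu, i_sig, i_beta0, i_beta1, i_gamma, i_gamma2,
      i_lambda, i_zeta0, i_zeta1, i_g0, i_g1, i_g2, npar;

  int cell(int j, int k, int M) const { return (M * K + k) * J + j; }
  int jk(int j, int k) const { return k * J + j; }
  int g0idx(int l, int k, int M) const { return (M * K + k) * 2 + l; }
};

static double ldnorm(double x, double mu, double var) {
  return -0.5 * std::log(2.0 * M_PI * var) - (x - mu) * (x - mu) / (2.0 * var);
}
static double ldgamma_sr(double x, double shape, double rate) {
  if (x <= 0.0) return R_NegInf;
  return shape * std::log(rate) - R::lgammafn(shape) +
         (shape - 1.0) * std::log(x) - rate * x;
}
static double ldinvgamma(double x, double a, double b) {
  if (x <= 0.0) return R_NegInf;
  return a * std::log(b) - R::lgammafn(a) - (a + 1.0) * std::log(x) - b / x;
}
static double ldcauchy0(double x, double s) {
  return -std::log(M_PI * s * (1.0 + (x / s) * (x / s)));
}
static double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static double softplus(double x) {
  return x > 35.0 ? x : std::log1p(std::exp(x));
}

static Model make_model(const List& spec) {
  Model m;
  m.J = as<int>(spec["J"]);
  m.K = as<int>(spec["K"]);
  m.variant = as<int>(spec["variant"]);
  m.use_lik = as<bool>(spec["use_lik"]);
  m.n_cell = as<std::vector<double>>(spec["n_cell"]);
  m.sz     = as<std::vector<double>>(spec["sum_z"]);
  m.sz2    = as<std::vector<double>>(spec["sum_z2"]);
  m.y0     = as<std::vector<double>>(spec["y0"]);
  m.y1     = as<std::vector<double>>(spec["y1"]);
  m.y2     = as<std::vector<double>>(spec["y2"]);
  m.n_jk   = as<std::vector<double>>(spec["n_jk"]);
  m.x_jk   = as<std::vector<double>>(spec["x_jk"]);
  m.d      = as<std::vector<double>>(spec["d_scaled"]);
  m.zeta0k = as<std::vector<double>>(spec["zeta0"]);
  m.tau2 = as<double>(spec["tau_sq"]);
  m.se0  = as<double>(spec["sigma_e0_sq"]);
  m.se1  = as<double>(spec["sigma_e1_sq"]);
  m.a_shape = as<double>(spec["alpha_shape"]);
  m.a_rate  = as<double>(spec["alpha_rate"]);
  m.d_shape = as<double>(spec["delta_shape"]);
  m.d_rate  = as<double>(spec["delta_rate"]);
  NumericVector ig = spec["sigma_z_ig"];
  m.ig_a = ig[0]; m.ig_b = ig[1];
  m.nu_sd    = as<double>(spec["nu_sd"]);
  m.b1_scale = as<double>(spec["beta1_scale"]);
  m.g_scale  = as<double>(spec["gamma_scale"]);
  m.g2_scale = as<double>(spec["gamma2_scale"]);
  m.b0_mean  = as<double>(spec["beta0_mean"]);
  m.b0_sd    = as<double>(spec["beta0_sd"]);
  m.lam_upper = as<double>(spec["lambda_upper"]);
  m.mu_scale  = as<double>(spec["mu_scale"]);
  m.alt2_int_sd = as<double>(spec["alt2_intercept_sd"]);

  int J = m.J, K = m.K;
  m.i_alpha = 0;
  m.i_delta = K;
  m.i_nu    = K + 1;
  m.i_sig   = K + 2;
  m.i_beta0 = K + 3;
  m.i_beta1 = 2 * K + 3;
  if (m.variant == ALT2) {
    m.i_g0 = 2 * K + 4;
    m.i_g1 = m.i_g0 + 2 * K * 2;
    m.i_g2 = m.i_g1 + 1;
    m.npar = m.i_g2 + 1;
    m.i_gamma = m.i_gamma2 = m.i_lambda = m.i_zeta0 = m.i_zeta1 = -1;
  } else {
    m.i_gamma  = 2 * K + 4;
    m.i_gamma2 = 2 * K + 5;                 // present but inert unless DOSE_ADJ
    m.i_lambda = 2 * K + 6;
    m.i_zeta0  = 2 * K + 7;
    m.i_zeta1  = m.i_zeta0 + J * K;
    m.npar     = m.i_zeta1 + J * K;
    m.i_g0 = m.i_g1 = m.i_g2 = -1;
  }
  return m;
}

// Full log posterior (likelihood terms from sufficient statistics + priors).
static double logpost(const Model& m, const std::vector<double>& p) {
  const int J = m.J, K = m.K;
  const double delta = p[m.i_delta], nu = p[m.i_nu], sig = p[m.i_sig];
  const double beta1 = p[m.i_beta1];

  for (int k = 0; k < K; k++) if (p[m.i_alpha + k] <= 0.0) return R_NegInf;
  if (delta <= 0.0 || nu <= 0.0 || sig <= 0.0) return R_NegInf;

  double gamma = 0.0, gamma2 = 0.0, lambda = 0.0;
  if (m.variant != ALT2) {
    gamma = p[m.i_gamma]; gamma2 = p[m.i_gamma2]; lambda = p[m.i_lambda];
    if (gamma <= 0.0 || lambda <= 0.0 || lambda >= m.lam_upper) return R_NegInf;
    for (int c = 0; c < J * K; c++) {
      if (p[m.i_zeta1 + c] <= p[m.i_zeta0 + c]) return R_NegInf;
    }
  } else {
    for (int k = 0; k < K; k++) {
      for (int M = 0; M < 2; M++) {
        if (p[m.i_g0 + m.g0idx(0, k, M)] >= p[m.i_g0 + m.g0idx(1, k, M)])
          return R_NegInf;
      }
      for (int l = 0; l < 2; l++) {  // marker-positive shifted toward response
        if (p[m.i_g0 + m.g0idx(l, k, 0)] <= p[m.i_g0 + m.g0idx(l, k, 1)])
          return R_NegInf;
      }
    }
  }

  // mean immune response per (j,k), marker-negative; subgroup factor exp(delta)
  std::vector<double> mu0(J * K);
  const double edelta = std::exp(delta);
  for (int k = 0; k < K; k++) {
    const double ak = p[m.i_alpha + k];
    for (int j = 0; j < J; j++) {
      mu0[m.jk(j, k)] = ak * (1.0 - std::exp(-nu * m.d[j]));
    }
  }

  double lp = 0.0;
  const bool use_z = m.use_lik && m.variant != ALT1;

  if (use_z) {
    for (int M = 0; M < 2; M++) {
      const double f = (M == 1) ? edelta : 1.0;
      for (int k = 0; k < K; k++) {
        for (int j = 0; j < J; j++) {
          const int c = m.cell(j, k, M);
          const double n = m.n_cell[c];
          if (n == 0.0) continue;
          const double mu = f * mu0[m.jk(j, k)];
          lp += -0.5 * n * std::log(2.0 * M_PI * sig) -
                (m.sz2[c] - 2.0 * mu * m.sz[c] + n * mu * mu) / (2.0 * sig);
        }
      }
    }
  }

  if (m.use_lik) {
    for (int k = 0; k < K; k++) {
      const double b0 = p[m.i_beta0 + k];
      for (int j = 0; j < J; j++) {
        const int c = m.jk(j, k);
        if (m.n_jk[c] == 0.0) continue;
        const double eta = b0 + beta1 * m.d[j];
        lp += m.x_jk[c] * eta - m.n_jk[c] * softplus(eta);
      }
    }
    if (m.variant != ALT2) {
      for (int M = 0; M < 2; M++) {
        for (int k = 0; k < K; k++) {
          for (int j = 0; j < J; j++) {
            const int c = m.cell(j, k, M);
            const double ny = m.y0[c] + m.y1[c] + m.y2[c];
            if (ny == 0.0) continue;
            const double z = p[m.i_zeta0 + m.jk(j, k) + (M == 1 ? J * K : 0)];
            // note zeta layout: zeta0 block M=0, zeta1 block M=1
            const double q2 = expit(z), qpos = expit(lambda + z);
            const double q1 = qpos - q2, q0 = 1.0 - qpos;
            if (m.y0[c] > 0.0) lp += (q0 > 0.0) ? m.y0[c] * std::log(q0) : R_NegInf;
            if (m.y1[c] > 0.0) lp += (q1 > 0.0) ? m.y1[c] * std::log(q1) : R_NegInf;
            if (m.y2[c] > 0.0) lp += (q2 > 0.0) ? m.y2[c] * std::log(q2) : R_NegInf;
            if (!R_finite(lp)) return R_NegInf;
          }
        }
      }
    } else {
      const double g1 = p[m.i_g1], g2c = p[m.i_g2];
      for (int M = 0; M < 2; M++) {
        const double f = (M == 1) ? edelta : 1.0;
        for (int k = 0; k < K; k++) {
          for (int j = 0; j < J; j++) {
            const int c = m.cell(j, k, M);
            const double ny = m.y0[c] + m.y1[c] + m.y2[c];
            if (ny == 0.0) continue;
            const double mt = f * mu0[m.jk(j, k)] / m.mu_scale;
            const double eta = g1 * mt + g2c * mt * mt;
            const double le0 = expit(p[m.i_g0 + m.g0idx(0, k, M)] + eta);
            const double le1 = expit(p[m.i_g0 + m.g0idx(1, k, M)] + eta);
            const double q0 = le0, q1 = le1 - le0, q2 = 1.0 - le1;
            if (m.y0[c] > 0.0) lp += (q0 > 0.0) ? m.y0[c] * std::log(q0) : R_NegInf;
            if (m.y1[c] > 0.0) lp += (q1 > 0.0) ? m.y1[c] * std::log(q1) : R_NegInf;
            if (m.y2[c] > 0.0) lp += (q2 > 0.0) ? m.y2[c] * std::log(q2) : R_NegInf;
            if (!R_finite(lp)) return R_NegInf;
          }
        }
      }
    }
  }

  // priors
  for (int k = 0; k < K; k++) {
    lp += ldgamma_sr(p[m.i_alpha + k], m.a_shape, m.a_rate);
    lp += ldnorm(p[m.i_beta0 + k], m.b0_mean, m.b0_sd * m.b0_sd);
  }
  lp += ldgamma_sr(delta, m.d_shape, m.d_rate);
  lp += ldnorm(nu, 0.0, m.nu_sd * m.nu_sd) + M_LN2;  // truncated to nu > 0
  lp += ldinvgamma(sig, m.ig_a, m.ig_b);
  lp += ldcauchy0(beta1, m.b1_scale);

  if (m.variant != ALT2) {
    lp += ldcauchy0(gamma, m.g_scale) + M_LN2;       // truncated to gamma > 0
    if (m.variant == DOSE_ADJ) lp += ldcauchy0(gamma2, m.g2_scale);
    lp += -std::log(m.lam_upper);
    for (int k = 0; k < K; k++) {
      lp += ldnorm(p[m.i_zeta0 + m.jk(0, k)], m.zeta0k[k], m.tau2);
      for (int j = 1; j < J; j++) {
        double mean = p[m.i_zeta0 + m.jk(j - 1, k)];
        if (m.variant == ALT1) {
          mean += gamma * (m.d[j] - m.d[j - 1]);
        } else {
          mean += gamma * (mu0[m.jk(j, k)] - mu0[m.jk(j - 1, k)]) / m.mu_scale;
          if (m.variant == DOSE_ADJ) mean += gamma2 * (m.d[j] - m.d[j - 1]);
        }
        lp += ldnorm(p[m.i_zeta0 + m.jk(j, k)], mean, m.se0);
      }
      for (int j = 0; j < J; j++) {
        lp += ldnorm(p[m.i_zeta1 + m.jk(j, k)], p[m.i_zeta0 + m.jk(j, k)],
                     m.se1) + M_LN2;                 // truncation constant
      }
    }
  } else {
    for (int i = 0; i < 2 * K * 2; i++) {
      lp += ldnorm(p[m.i_g0 + i], 0.0, m.alt2_int_sd * m.alt2_int_sd);
    }
    lp += ldcauchy0(p[m.i_g1], m.g_scale);
    lp += ldcauchy0(p[m.i_g2], m.g_scale);
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_logpost(List spec, NumericVector par) {
  Model m = make_model(spec);
  if ((int)par.size() != m.npar) stop("parameter vector has wrong length");
  std::vector<double> p = as<std::vector<double>>(par);
  return logpost(m, p);
}

// [[Rcpp::export]]
List cpp_mcmc(List spec, NumericVector init, int n_burn, int n_keep, int thin,
              double init_step, int adapt_interval) {
  Model m = make_model(spec);
  if ((int)init.size() != m.npar) stop("init vector has wrong length");
  std::vector<double> p = as<std::vector<double>>(init);

  std::vector<int> kind(m.npar, RW);
  for (int k = 0; k < m.K; k++) kind[m.i_alpha + k] = LOGRW;
  kind[m.i_delta] = LOGRW;
  kind[m.i_nu] = LOGRW;
  kind[m.i_sig] = GIBBS_SIGMA;
  if (m.variant != ALT2) {
    kind[m.i_gamma] = LOGRW;
    if (m.variant != DOSE_ADJ) kind[m.i_gamma2] = -1;  // fixed at 0
  }

  std::vector<double> step(m.npar, init_step);
  std::vector<long> acc(m.npar, 0), tries(m.npar, 0);
  std::vector<long> acc_tot(m.npar, 0), tries_tot(m.npar, 0);

  const bool use_z = m.use_lik && m.variant != ALT1;
  double n_z = 0.0;
  if (use_z) for (double n : m.n_cell) n_z += n;

  RNGScope scope;
  double cur = logpost(m, p);
  if (!R_finite(cur)) stop("initial log-posterior is not finite");

  const int n_iter = n_burn + n_keep * thin;
  NumericMatrix draws(n_keep, m.npar);
  int stored = 0;

  for (int it = 0; it < n_iter; it++) {
    const bool burn = it < n_burn;
    for (int i = 0; i < m.npar; i++) {
      if (kind[i] == -1) continue;
      if (kind[i] == GIBBS_SIGMA) {
        double shape = m.ig_a, rate = m.ig_b;
        if (use_z) {
          // residual sum of squares from per-cell sufficient statistics
          const double delta = p[m.i_delta], nu = p[m.i_nu];
          const double edelta = std::exp(delta);
          double ssr = 0.0;
          for (int M = 0; M < 2; M++) {
            const double f = (M == 1) ? edelta : 1.0;
            for (int k = 0; k < m.K; k++) {
              const double ak = p[m.i_alpha + k];
              for (int j = 0; j < m.J; j++) {
                const int c = m.cell(j, k, M);
                if (m.n_cell[c] == 0.0) continue;
                const double mu = f * ak * (1.0 - std::exp(-nu * m.d[j]));
                ssr += m.sz2[c] - 2.0 * mu * m.sz[c] + m.n_cell[c] * mu * mu;
              }
            }
          }
          shape += 0.5 * n_z;
          rate += 0.5 * std::max(ssr, 0.0);
        }
        p[m.i_sig] = 1.0 / R::rgamma(shape, 1.0 / rate);
        cur = logpost(m, p);
        continue;
      }
      const double old = p[i];
      double lratio = 0.0;
      if (kind[i] == LOGRW) {
        p[i] = old * std::exp(step[i] * R::norm_rand());
        lratio = std::log(p[i]) - std::log(old);   // Jacobian of log-scale walk
      } else {
        p[i] = old + step[i] * R::norm_rand();
      }
      const double prop = logpost(m, p);
      tries[i]++; tries_tot[i] += burn ? 0 : 1;
      if (std::log(R::unif_rand()) < prop - cur + lratio) {
        cur = prop;
        acc[i]++; acc_tot[i] += burn ? 0 : 1;
      } else {
        p[i] = old;
      }
    }
    if (burn && adapt_interval > 0 && (it + 1) % adapt_interval == 0) {
      for (int i = 0; i < m.npar; i++) {
        if (kind[i] == RW || kind[i] == LOGRW) {
          if (tries[i] > 0) {
            const double r = (double)acc[i] / (double)tries[i];
            if (r < 0.30) step[i] *= 0.8;
            else if (r > 0.40) step[i] *= 1.25;
            step[i] = std::min(std::max(step[i], 1e-3), 10.0);
          }
          acc[i] = 0; tries[i] = 0;
        }
      }
    }
    if (!burn && ((it - n_burn + 1) % thin == 0) && stored < n_keep) {
      for (int i = 0; i < m.npar; i++) draws(stored, i) = p[i];
      stored++;
    }
  }

  NumericVector arate(m.npar), steps(m.npar);
  for (int i = 0; i < m.npar; i++) {
    arate[i] = tries_tot[i] > 0 ? (double)acc_tot[i] / (double)tries_tot[i]
                                : NA_REAL;
    steps[i] = step[i];
  }
  return List::create(_["draws"] = draws, _["accept"] = arate,
                      _["steps"] = steps);
}
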