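#' Immune-response model parameters
#'
#' Parameters of the plateau model for the mean immune response,
#' `mu_Z((j,k),M) = alpha_k * exp(delta * M) * (1 - exp(-nu * d_j))`, where
#' `Z` is the increase in log immune activity from baseline. `alpha_k` is the
#' maximum mean immune response achievable under schedule `k` for
#' marker-negative patients, `exp(delta)` the marker-positive/negative ratio
#' of that maximum, `nu` the dose rate at which the plateau is approached, and
#' `sigma_z_sq` the residual variance of `Z`.
#'
#' @param alpha Positive numeric vector, one entry per schedule.
#' @param delta Positive scalar (log subgroup ratio).
#' @param nu Positive scalar dose-rate.
#' @param sigma_z_sq Positive residual variance.
#' @return A list of class `dsd_immune_params`.
#' @export
immune_params <- function(alpha, delta, nu, sigma_z_sq = 1) {
  if (!is.numeric(alpha) || any(alpha <= 0)) abort("`alpha` must be positive")
  check_scalar_number(delta, "delta", 0, strict_lower = TRUE)
  check_scalar_number(nu, "nu", 0, strict_lower = TRUE)
  check_scalar_number(sigma_z_sq, "sigma_z_sq", 0, strict_lower = TRUE)
  structure(list(alpha = as.numeric(alpha), delta = delta, nu = nu,
                 sigma_z_sq = sigma_z_sq),
            class = "dsd_immune_params")
}

#' Toxicity model parameters
#'
#' Parameters of the schedule-specific logistic model
#' `logit p(j,k) = beta0_k + beta1 * d_j` for the probability of a
#' dose-limiting toxicity, shared across biomarker subgroups.
#'
#' @param beta0 Numeric vector of per-schedule intercepts.
#' @param beta1 Scalar dose slope (sign unconstrained, so toxicity may be
#'   partially ordered across schedules).
#' @return A list of class `dsd_toxicity_params`.
#' @export
toxicity_params <- function(beta0, beta1) {
  if (!is.numeric(beta0) || any(!is.finite(beta0))) abort("`beta0` must be finite")
  check_scalar_number(beta1, "beta1")
  structure(list(beta0 = as.numeric(beta0), beta1 = beta1),
            class = "dsd_toxicity_params")
}

#' Efficacy model parameters
#'
#' Parameters of the ordinal efficacy model. `zeta[j,k,M]` is the logit of
#' the CR/PR probability at combination `(j,k)` in subgroup `M` (+1 in the
#' array index); the marker-positive value is constrained above the
#' marker-negative one. `lambda > 0` is the proportional-odds shift giving
#' `logit Pr(Y > 0) = lambda + zeta`. `gamma` is the average effect of the
#' (scaled) mean immune response in the dynamic model linking adjacent doses;
#' `gamma2` is the optional direct dose effect of the dose-adjusted variant.
#'
#' @param zeta Numeric array `J x K x 2` with `zeta[, , 2] > zeta[, , 1]`.
#' @param gamma Positive scalar immune-response effect.
#' @param lambda Positive proportional-odds shift.
#' @param gamma2 Optional direct dose effect (default 0).
#' @return A list of class `dsd_efficacy_params`.
#' @export
efficacy_params <- function(zeta, gamma, lambda, gamma2 = 0) {
  if (length(dim(zeta)) != 3L || dim(zeta)[3] != 2L) {
    abort("`zeta` must be a J x K x 2 array")
  }
  if (any(zeta[, , 2] <= zeta[, , 1])) {
    abort("`zeta` must satisfy zeta[j,k,M=1] > zeta[j,k,M=0] for every (j,k)")
  }
  check_scalar_number(gamma, "gamma", 0, strict_lower = TRUE)
  check_scalar_number(lambda, "lambda", 0, strict_lower = TRUE)
  check_scalar_number(gamma2, "gamma2")
  structure(list(zeta = zeta, gamma = gamma, lambda = lambda, gamma2 = gamma2),
            class = "dsd_efficacy_params")
}

#' Full parameter state
#'
#' Collects the immune-response, toxicity, and efficacy parameter blocks into
#' the joint parameter vector Theta of the model.
#'
#' @param immune A [immune_params()] object.
#' @param tox A [toxicity_params()] object.
#' @param eff An [efficacy_params()] object.
#' @return A list of class `dsd_parameter_state`.
#' @export
parameter_state <- function(immune, tox, eff) {
  stopifnot(inherits(immune, "dsd_immune_params"),
            inherits(tox, "dsd_toxicity_params"),
            inherits(eff, "dsd_efficacy_params"))
  if (length(immune$alpha) != length(tox$beta0) ||
      dim(eff$zeta)[2] != length(tox$beta0)) {
    abort("schedule dimensions of the parameter blocks disagree")
  }
  structure(list(immune = immune, tox = tox, eff = eff),
            class = "dsd_parameter_state")
}

#' Efficacy-model hyperparameters
#'
#' Clinician-elicited anchors of the dynamic efficacy model: `zeta0` is the
#' prior mean of the lowest-dose CR/PR logit per schedule (e.g. -2.2 for a
#' best guess of 10% CR/PR), `tau_sq` its prior variance, and
#' `sigma_e0_sq` / `sigma_e1_sq` the innovation variances of the
#' across-dose random walk and the across-subgroup truncated-normal link.
#'
#' @param zeta0 Numeric vector (recycled to `K`) of prior means.
#' @param tau_sq,sigma_e0_sq,sigma_e1_sq Positive variances.
#' @param K Number of schedules `zeta0` is recycled to.
#' @return A list of class `dsd_model_hyper`.
#' @export
model_hyper <- function(zeta0 = -2.2, tau_sq = 1, sigma_e0_sq = 0.3,
                        sigma_e1_sq = 0.3, K = 3L) {
  check_scalar_number(tau_sq, "tau_sq", 0, strict_lower = TRUE)
  check_scalar_number(sigma_e0_sq, "sigma_e0_sq", 0, strict_lower = TRUE)
  check_scalar_number(sigma_e1_sq, "sigma_e1_sq", 0, strict_lower = TRUE)
  structure(list(zeta0 = rep_len(as.numeric(zeta0), K), tau_sq = tau_sq,
                 sigma_e0_sq = sigma_e0_sq, sigma_e1_sq = sigma_e1_sq),
            class = "dsd_model_hyper")
}

#' Weakly-informative prior specification
#'
#' Builds the full prior from clinician elicitations: `alpha_hat` (expected
#' maximum mean immune response per schedule, marker-negative), `r_hat`
#' (expected marker-positive/negative ratio of that maximum), and `m_mu`
#' (maximum plausible mean immune response, used to scale the covariate of
#' the immune-response effect `gamma`). Gamma priors for `alpha_k` and
#' `delta` match the elicited mean with SD `sd_inflation` times the mean
#' (shape `1/sd_inflation^2`); `sigma_z_sq` gets a vague inverse-Gamma;
#' `nu` a positive-truncated normal scaled so that a 2-SD move of the
#' standardized dose shifts the plateau-model regression by less than 4.6
#' (the logit-scale change from 1% to 99% saturation); `beta1` and `gamma`
#' get heavy-tailed Cauchy priors on 0.5-SD-scaled covariates; `beta0_k`
#' normal priors centered at a 1.8% no-dose toxicity; `lambda` a uniform
#' prior wide enough that `Pr(Y > 0)` can reach 0.99 whenever
#' `Pr(Y = 2) >= 0.03`.
#'
#' @param alpha_hat Elicited maximum mean immune response (scalar, applied to
#'   every schedule).
#' @param r_hat Elicited subgroup ratio (> 1).
#' @param m_mu Elicited maximum possible mean immune response.
#' @param sd_inflation Prior-SD multiplier (3 = default vague priors; 5
#'   reproduces the diffuse sensitivity setting).
#' @param sigma_z_ig Length-2 inverse-Gamma (shape, rate) for `sigma_z_sq`.
#' @param nu_sd Truncated-normal scale for `nu`.
#' @param beta1_scale,gamma_scale Cauchy scales.
#' @param beta0_mean,beta0_sd Normal prior for the toxicity intercepts.
#' @param lambda_upper Upper bound of the uniform prior for `lambda`.
#' @return A list of class `dsd_prior_spec` with the derived Gamma
#'   shape/rate pairs (`alpha_shape`, `alpha_rate`, `delta_shape`,
#'   `delta_rate`) and all scale parameters.
#' @examples
#' ps <- prior_spec()
#' c(ps$alpha_shape / ps$alpha_rate, sqrt(ps$alpha_shape) / ps$alpha_rate)  # 20, 60
#' @export
prior_spec <- function(alpha_hat = 20, r_hat = 1.5, m_mu = 30,
                       sd_inflation = 3, sigma_z_ig = c(0.1, 0.1),
                       nu_sd = 2.3, beta1_scale = 2.5, gamma_scale = 2.5,
                       beta0_mean = -4, beta0_sd = 1, lambda_upper = 8) {
  check_scalar_number(alpha_hat, "alpha_hat", 0, strict_lower = TRUE)
  check_scalar_number(r_hat, "r_hat", 1, strict_lower = TRUE)
  check_scalar_number(m_mu, "m_mu", 0, strict_lower = TRUE)
  check_scalar_number(sd_inflation, "sd_inflation", 0, strict_lower = TRUE)
  shape <- 1 / sd_inflation^2
  structure(list(
    alpha_hat = alpha_hat, r_hat = r_hat, m_mu = m_mu,
    sd_inflation = sd_inflation,
    alpha_shape = shape, alpha_rate = shape / alpha_hat,
    delta_shape = shape, delta_rate = shape / log(r_hat),
    sigma_z_ig = sigma_z_ig,
    nu_sd = nu_sd, beta1_scale = beta1_scale, gamma_scale = gamma_scale,
    gamma2_scale = beta1_scale,
    beta0_mean = beta0_mean, beta0_sd = beta0_sd,
    lambda_upper = lambda_upper,
    alt2_intercept_sd = 2.5,
    mu_scale = m_mu / 2), class = "dsd_prior_spec")
}
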