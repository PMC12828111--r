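#' Mean immune response under the plateau model
#'
#' Evaluates `alpha_k * exp(delta * M) * (1 - exp(-nu * d_j))`, the mean
#' increase in log immune activity at dose `j`, schedule `k`, subgroup `M`.
#' The response is 0 at dose 0, increases with dose, and saturates at
#' `alpha_k * exp(delta * M)`.
#'
#' @param params An [immune_params()] object.
#' @param grid A [dose_grid()].
#' @param j,k,M Dose index, schedule index (1-based), subgroup (0/1);
#'   vectors are recycled together.
#' @param dose_scale `"scaled"` (default; the model's internal 0.5-SD dose
#'   scale) or `"raw"` to evaluate on raw drug amounts.
#' @return Numeric vector of mean immune responses.
#' @export
mean_immune_response <- function(params, grid, j, k, M,
                                 dose_scale = c("scaled", "raw")) {
  dose_scale <- match.arg(dose_scale)
  d <- if (dose_scale == "scaled") grid$scaled else grid$raw
  if (any(j < 1L | j > grid$J) || any(k < 1L | k > grid$K)) {
    abort("dose/schedule index out of range")
  }
  if (any(!M %in% subgroup_levels())) abort("`M` must be 0 or 1")
  params$alpha[k] * exp(params$delta * M) * (1 - exp(-params$nu * d[j]))
}

#' Toxicity probability under the logistic model
#'
#' `expit(beta0_k + beta1 * d_j)`, shared across biomarker subgroups.
#'
#' @inheritParams mean_immune_response
#' @param params A [toxicity_params()] object.
#' @return Numeric vector of DLT probabilities.
#' @export
toxicity_probability <- function(params, grid, j, k,
                                 dose_scale = c("scaled", "raw")) {
  dose_scale <- match.arg(dose_scale)
  d <- if (dose_scale == "scaled") grid$scaled else grid$raw
  if (any(j < 1L | j > grid$J) || any(k < 1L | k > grid$K)) {
    abort("dose/schedule index out of range")
  }
  expit(params$beta0[k] + params$beta1 * d[j])
}

#' Ordinal efficacy category probabilities
#'
#' Maps the CR/PR logit `zeta` and the proportional-odds shift `lambda` to
#' the category probabilities of the ordinal response
#' (PD, SD, CR/PR) = (q0, q1, q2):
#' `q2 = expit(zeta)`, `q1 = expit(lambda + zeta) - expit(zeta)`,
#' `q0 = 1 - expit(lambda + zeta)`.
#'
#' @param zeta Numeric vector of CR/PR logits.
#' @param lambda Positive proportional-odds shift (scalar or vector).
#' @return A tibble with columns `q0`, `q1`, `q2` (rows sum to 1).
#' @examples
#' efficacy_category_probs(qlogis(0.03), lambda = 8)
#' @export
efficacy_category_probs <- function(zeta, lambda) {
  if (any(lambda < 0)) abort("`lambda` must be nonnegative")
  q2 <- expit(zeta)
  qpos <- expit(lambda + zeta)
  tibble(q0 = 1 - qpos, q1 = qpos - q2, q2 = q2)
}

#' Dynamic-model prior mean for the next-dose efficacy logit
#'
#' The Bayesian dynamic efficacy model centers the CR/PR logit of dose `j`
#' (marker-negative chain) on that of dose `j - 1` in the same schedule plus
#' an increment driven by the immune response:
#' `zeta_prev + gamma * (mu_Z(j,k,0) - mu_Z(j-1,k,0)) / mu_scale` for the
#' proposed model; the dose-adjusted variant adds `gamma2 * (d_j - d_{j-1})`;
#' the immune-response-free comparator (`"alternative1"`) replaces the
#' immune-response increment with the dose increment
#' `gamma * (d_j - d_{j-1})`.
#'
#' @param variant One of `"proposed"`, `"dose_adjusted"`, `"alternative1"`.
#' @param zeta_prev Efficacy logit of the next lower dose, same schedule.
#' @param immune An [immune_params()] object (ignored by `"alternative1"`).
#' @param grid A [dose_grid()].
#' @param gamma Immune-response (or dose) effect.
#' @param j,k Dose index (must be >= 2) and schedule index.
#' @param gamma2 Direct dose effect for `"dose_adjusted"`.
#' @param mu_scale Divisor applied to mean immune responses before they are
#'   multiplied by `gamma` (half the elicited maximum, `m_mu / 2`); use 1
#'   for unscaled immune responses.
#' @param dose_scale Dose scale for both the plateau model and the dose
#'   increments (`"scaled"` by default).
#' @return The prior mean for `zeta_(j,k),0`.
#' @export
efficacy_dynamic_prior_mean <- function(variant, zeta_prev, immune, grid,
                                        gamma, j, k, gamma2 = 0,
                                        mu_scale = 1,
                                        dose_scale = c("scaled", "raw")) {
  variant <- match.arg(variant, c("proposed", "dose_adjusted", "alternative1"))
  dose_scale <- match.arg(dose_scale)
  if (any(j < 2L)) {
    abort("the dynamic prior mean is defined for j >= 2; dose 1 is anchored at zeta0")
  }
  d <- if (dose_scale == "scaled") grid$scaled else grid$raw
  if (variant == "alternative1") {
    return(zeta_prev + gamma * (d[j] - d[j - 1L]))
  }
  dmu <- (mean_immune_response(immune, grid, j, k, 0L, dose_scale) -
            mean_immune_response(immune, grid, j - 1L, k, 0L, dose_scale)) / mu_scale
  out <- zeta_prev + gamma * dmu
  if (variant == "dose_adjusted") out <- out + gamma2 * (d[j] - d[j - 1L])
  out
}

#' Efficacy category probabilities under the proportional-odds comparator
#'
#' The parametric comparator models the cumulative logits of the ordinal
#' response directly:
#' `logit Pr(Y <= l) = intercept_l + gamma1 * mu_z + gamma2 * mu_z^2` for
#' `l = 0, 1`, with ordered intercepts per (schedule, subgroup).
#'
#' @param intercepts Numeric vector of 2 strictly increasing cut-point
#'   intercepts for one (schedule, subgroup).
#' @param gamma1,gamma2 Shared regression coefficients on the (scaled) mean
#'   immune response and its square.
#' @param mu_z Mean immune response value(s) at which to evaluate.
#' @return A tibble with columns `q0`, `q1`, `q2`.
#' @export
alt2_efficacy_probs <- function(intercepts, gamma1, gamma2, mu_z) {
  if (length(intercepts) != 2L || diff(intercepts) <= 0) {
    abort("`intercepts` must be 2 strictly increasing cut-points")
  }
  eta <- gamma1 * mu_z + gamma2 * mu_z^2
  le0 <- expit(intercepts[1] + eta)
  le1 <- expit(intercepts[2] + eta)
  tibble(q0 = le0, q1 = le1 - le0, q2 = 1 - le1)
}
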