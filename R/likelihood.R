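# Joint likelihood and prior density on the R side. These are the reference
# implementations used to validate the compiled sampler's log-posterior; they
# favour clarity over speed (the sampler itself works from per-cell
# sufficient statistics in C++).

ld_invgamma <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

ld_cauchy <- function(x, scale) {
  stats::dcauchy(x, 0, scale, log = TRUE)
}

#' Log-likelihood of one patient record
#'
#' The per-patient likelihood factorizes into independent immune-response,
#' efficacy, and toxicity terms:
#' a normal density for `z`, a categorical probability for the ordinal `y`
#' (from [efficacy_category_probs()], or the proportional-odds comparator if
#' `theta` carries an `alt2` block), and a Bernoulli probability for `x`
#' (from [toxicity_probability()]).
#'
#' @param theta A [parameter_state()]; for the proportional-odds comparator
#'   a list with fields `immune`, `tox`, and `alt2 = list(g0, gamma1,
#'   gamma2)` where `g0` is a `2 x K x 2` array of ordered intercepts.
#' @param grid A [dose_grid()].
#' @param o A one-row data frame or list with fields `dose_index`,
#'   `schedule_index`, `subgroup`, `z`, `x`, `y`.
#' @param mu_scale Immune-response divisor used by the proportional-odds
#'   comparator's regression (ignored otherwise).
#' @param include_z Set `FALSE` to drop the immune-response term (the
#'   immune-response-free comparator design).
#' @return The patient's log-likelihood contribution.
#' @export
log_likelihood_patient <- function(theta, grid, o, mu_scale = 1,
                                   include_z = TRUE) {
  j <- as.integer(o$dose_index); k <- as.integer(o$schedule_index)
  M <- as.integer(o$subgroup)
  ll <- 0
  if (include_z) {
    mu <- mean_immune_response(theta$immune, grid, j, k, M)
    ll <- ll + dnorm(o$z, mu, sqrt(theta$immune$sigma_z_sq), log = TRUE)
  }
  p <- toxicity_probability(theta$tox, grid, j, k)
  ll <- ll + ifelse(o$x == 1L, log(p), log1p(-p))
  if (!is.null(theta$alt2)) {
    mu_t <- mean_immune_response(theta$immune, grid, j, k, M) / mu_scale
    q <- alt2_efficacy_probs(theta$alt2$g0[, k, M + 1L],
                             theta$alt2$gamma1, theta$alt2$gamma2, mu_t)
  } else {
    q <- efficacy_category_probs(theta$eff$zeta[j, k, M + 1L], theta$eff$lambda)
  }
  ll + log(c(q$q0, q$q1, q$q2)[o$y + 1L])
}

#' Log-likelihood of a set of patient records
#'
#' @inheritParams log_likelihood_patient
#' @param data Tibble of patient records (columns `dose_index`,
#'   `schedule_index`, `subgroup`, `z`, `x`, `y`).
#' @return Total log-likelihood.
#' @export
log_likelihood <- function(theta, grid, data, mu_scale = 1, include_z = TRUE) {
  if (nrow(data) == 0L) return(0)
  sum(vapply(seq_len(nrow(data)), function(i) {
    log_likelihood_patient(theta, grid, data[i, ], mu_scale, include_z)
  }, numeric(1)))
}

#' Log prior density of a parameter state
#'
#' Sums the log prior densities of every component of Theta: Gamma
#' (shape/rate) for `alpha_k` and `delta`; inverse-Gamma for `sigma_z_sq`;
#' positive-truncated normal for `nu`; Cauchy for `beta1` (and, when
#' present, `gamma2`); positive-truncated Cauchy for `gamma`; normal for
#' each `beta0_k`; uniform for `lambda`; and the dynamic efficacy terms —
#' `N(zeta0_k, tau_sq)` anchoring the lowest dose, `N(dynamic mean,
#' sigma_e0_sq)` for higher doses of the marker-negative chain, and the
#' truncated normal `N(zeta_(j,k),0, sigma_e1_sq) I(zeta1 > zeta0)`
#' (including its log 2 normalizing constant) linking subgroups at every
#' dose. Constraint violations return `-Inf`.
#'
#' @param theta A [parameter_state()].
#' @param hyper A [model_hyper()].
#' @param prior A [prior_spec()].
#' @param grid A [dose_grid()].
#' @param variant `"proposed"`, `"dose_adjusted"`, or `"alternative1"`
#'   (selects the dynamic-mean form, see
#'   [efficacy_dynamic_prior_mean()]).
#' @return The log prior density (may be `-Inf`).
#' @export
log_prior <- function(theta, hyper, prior, grid,
                      variant = c("proposed", "dose_adjusted", "alternative1")) {
  variant <- match.arg(variant)
  im <- theta$immune; tox <- theta$tox; eff <- theta$eff
  if (any(im$alpha <= 0) || im$delta <= 0 || im$nu <= 0 ||
      im$sigma_z_sq <= 0 || eff$gamma <= 0 ||
      eff$lambda <= 0 || eff$lambda >= prior$lambda_upper ||
      any(eff$zeta[, , 2] <= eff$zeta[, , 1])) {
    return(-Inf)
  }
  lp <- sum(stats::dgamma(im$alpha, prior$alpha_shape, prior$alpha_rate, log = TRUE)) +
    stats::dgamma(im$delta, prior$delta_shape, prior$delta_rate, log = TRUE) +
    ld_invgamma(im$sigma_z_sq, prior$sigma_z_ig[1], prior$sigma_z_ig[2]) +
    dnorm(im$nu, 0, prior$nu_sd, log = TRUE) + log(2) +
    sum(dnorm(tox$beta0, prior$beta0_mean, prior$beta0_sd, log = TRUE)) +
    ld_cauchy(tox$beta1, prior$beta1_scale) +
    ld_cauchy(eff$gamma, prior$gamma_scale) + log(2) -
    log(prior$lambda_upper)
  if (variant == "dose_adjusted") {
    lp <- lp + ld_cauchy(eff$gamma2, prior$gamma2_scale)
  }
  se0 <- sqrt(hyper$sigma_e0_sq); se1 <- sqrt(hyper$sigma_e1_sq)
  for (k in seq_len(grid$K)) {
    lp <- lp + dnorm(eff$zeta[1, k, 1], hyper$zeta0[k], sqrt(hyper$tau_sq),
                     log = TRUE)
    for (j in seq_len(grid$J)[-1]) {
      m <- efficacy_dynamic_prior_mean(variant, eff$zeta[j - 1, k, 1],
                                       im, grid, eff$gamma, j, k,
                                       gamma2 = eff$gamma2,
                                       mu_scale = prior$mu_scale)
      lp <- lp + dnorm(eff$zeta[j, k, 1], m, se0, log = TRUE)
    }
    for (j in seq_len(grid$J)) {
      lp <- lp + dnorm(eff$zeta[j, k, 2], eff$zeta[j, k, 1], se1, log = TRUE) +
        log(2)  # truncation to zeta1 > zeta0 halves the mass
    }
  }
  lp
}
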