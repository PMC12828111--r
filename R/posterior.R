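#' MCMC settings
#'
#' @param n_burn Burn-in sweeps (step sizes adapt only during burn-in,
#'   targeting 30-40% acceptance, and are frozen afterwards).
#' @param n_keep Retained draws.
#' @param thin Thinning interval.
#' @param step Initial random-walk step scale for every block.
#' @param adapt_interval Sweeps between step-size adaptations.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used inside trial simulation so one trial seed governs
#'   everything).
#' @return A list of class `dsd_mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 1000L, n_keep = 2000L, thin = 1L,
                        step = 0.3, adapt_interval = 50L, seed = NULL) {
  n_burn <- as.integer(n_burn); n_keep <- as.integer(n_keep)
  thin <- as.integer(thin)
  if (n_burn < 0L || n_keep < 1L || thin < 1L) {
    abort("need n_burn >= 0, n_keep >= 1, thin >= 1")
  }
  structure(list(n_burn = n_burn, n_keep = n_keep, thin = thin, step = step,
                 adapt_interval = as.integer(adapt_interval), seed = seed),
            class = "dsd_mcmc_config")
}

variant_code <- function(variant) {
  match(variant, c("proposed", "dose_adjusted", "alternative1",
                   "alternative2")) - 1L
}

param_names <- function(grid, variant) {
  J <- grid$J; K <- grid$K
  base <- c(paste0("alpha_", seq_len(K)), "delta", "nu", "sigma_z_sq",
            paste0("beta0_", seq_len(K)), "beta1")
  if (variant == "alternative2") {
    g0 <- unlist(lapply(0:1, function(M) {
      unlist(lapply(seq_len(K), function(k) {
        paste0("gamma0_l", 0:1, "_k", k, "_M", M)
      }))
    }))
    c(base, g0, "gamma_eff1", "gamma_eff2")
  } else {
    z <- function(M) {
      unlist(lapply(seq_len(K), function(k)
        paste0("zeta_", seq_len(J), "_", k, "_", M)))
    }
    c(base, "gamma", "gamma2", "lambda", z(0), z(1))
  }
}

validate_patient_data <- function(data, grid) {
  need <- c("dose_index", "schedule_index", "subgroup", "z", "x", "y")
  if (!all(need %in% names(data))) {
    abort(paste("patient data needs columns:", paste(need, collapse = ", ")))
  }
  if (any(data$dose_index < 1L | data$dose_index > grid$J) ||
      any(data$schedule_index < 1L | data$schedule_index > grid$K)) {
    abort("dose/schedule index out of range for the grid")
  }
  if (any(!data$subgroup %in% 0:1) || any(!data$x %in% 0:1) ||
      any(!data$y %in% 0:2)) {
    abort("subgroup must be 0/1, x must be 0/1, y must be 0/1/2")
  }
  invisible(data)
}

suff_stats <- function(data, grid) {
  J <- grid$J; K <- grid$K
  idx_cell <- with(data, ((subgroup * K + (schedule_index - 1L)) * J +
                            (dose_index - 1L)) + 1L)
  idx_jk <- with(data, ((schedule_index - 1L) * J + (dose_index - 1L)) + 1L)
  nc <- J * K * 2L
  agg <- function(values, idx, n) {
    out <- numeric(n); t <- tapply(values, idx, sum)
    out[as.integer(names(t))] <- t; out
  }
  ones <- rep(1, nrow(data))
  list(n_cell = agg(ones, idx_cell, nc),
       sum_z = agg(data$z, idx_cell, nc),
       sum_z2 = agg(data$z^2, idx_cell, nc),
       y0 = agg(as.numeric(data$y == 0L), idx_cell, nc),
       y1 = agg(as.numeric(data$y == 1L), idx_cell, nc),
       y2 = agg(as.numeric(data$y == 2L), idx_cell, nc),
       n_jk = agg(ones, idx_jk, J * K),
       x_jk = agg(as.numeric(data$x), idx_jk, J * K))
}

model_spec <- function(grid, hyper, prior, variant, suff, use_lik = TRUE) {
  c(list(J = grid$J, K = grid$K, variant = variant_code(variant),
         use_lik = use_lik, d_scaled = grid$scaled,
         zeta0 = hyper$zeta0, tau_sq = hyper$tau_sq,
         sigma_e0_sq = hyper$sigma_e0_sq, sigma_e1_sq = hyper$sigma_e1_sq),
    prior[c("alpha_shape", "alpha_rate", "delta_shape", "delta_rate",
            "sigma_z_ig", "nu_sd", "beta1_scale", "gamma_scale",
            "gamma2_scale", "beta0_mean", "beta0_sd", "lambda_upper",
            "mu_scale", "alt2_intercept_sd")],
    suff)
}

init_params <- function(grid, hyper, prior, variant, data = NULL) {
  J <- grid$J; K <- grid$K
  sig0 <- if (!is.null(data) && nrow(data) > 1 && sd(data$z) > 0) {
    var(data$z)
  } else 1
  base <- c(rep(prior$alpha_hat, K), log(prior$r_hat),
            prior$nu_sd * qnorm(0.75), sig0,
            rep(prior$beta0_mean, K), 0)
  if (variant == "alternative2") {
    g0 <- c(rep(c(0, 1.5), K), rep(c(-0.5, 1.0), K))
    c(base, g0, 0, 0)
  } else {
    z0 <- rep(hyper$zeta0, each = J)
    c(base, prior$gamma_scale, 0, prior$lambda_upper / 2, z0, z0 + 0.1)
  }
}

# Map a parameter_state to the flat vector layout of the compiled sampler
# (dynamic-model variants only).
flatten_params <- function(theta, grid, variant = "proposed") {
  J <- grid$J; K <- grid$K
  zeta <- theta$eff$zeta
  c(theta$immune$alpha, theta$immune$delta, theta$immune$nu,
    theta$immune$sigma_z_sq, theta$tox$beta0, theta$tox$beta1,
    theta$eff$gamma, theta$eff$gamma2 %||% 0, theta$eff$lambda,
    as.vector(zeta[, , 1]), as.vector(zeta[, , 2]))
}

#' Sample the joint posterior by Metropolis-within-Gibbs
#'
#' Runs per-parameter random-walk Metropolis updates (log-scale proposals
#' for the positivity-constrained `alpha_k`, `delta`, `nu`, `gamma`; a
#' conjugate inverse-Gamma Gibbs draw for `sigma_z_sq`; rejection of
#' proposals violating truncations) on the joint posterior of the
#' immune-response, toxicity, and efficacy models. The likelihood enters
#' through per-cell sufficient statistics, so runtime is governed by chain
#' length, not the number of patients.
#'
#' @param data Tibble of patient records (`dose_index`, `schedule_index`,
#'   `subgroup`, `z`, `x`, `y`). Empty cells are dominated by the prior.
#' @param grid A [dose_grid()].
#' @param hyper A [model_hyper()].
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param variant Design variant; `"alternative1"` drops the
#'   immune-response likelihood term, `"alternative2"` swaps the dynamic
#'   efficacy model for the parametric proportional-odds comparator.
#' @param prior_only Internal testing hook: sample the generative prior by
#'   dropping all likelihood terms (allows empty `data`).
#' @return An object of class `dsd_posterior`: `draws` (matrix of retained
#'   draws, one named column per scalar), `accept` (post-burn-in acceptance
#'   rate per scalar), `variant`, `grid`, and configuration echoes.
#' @export
gibbs_sample <- function(data, grid, hyper = model_hyper(K = grid$K),
                         prior = prior_spec(), mcmc = mcmc_config(),
                         variant = c("proposed", "dose_adjusted",
                                     "alternative1", "alternative2"),
                         prior_only = FALSE) {
  variant <- match.arg(variant)
  if (is.null(data)) data <- tibble(dose_index = integer(), schedule_index =
                                      integer(), subgroup = integer(),
                                    z = numeric(), x = integer(), y = integer())
  if (nrow(data) == 0L && !prior_only) {
    abort("`data` is empty; use prior_only = TRUE to sample the prior")
  }
  validate_patient_data(data, grid)
  hyper$zeta0 <- rep_len(hyper$zeta0, grid$K)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  spec <- model_spec(grid, hyper, prior, variant, suff_stats(data, grid),
                     use_lik = !prior_only)
  init <- init_params(grid, hyper, prior, variant, data)
  for (try in 1:20) {
    if (is.finite(cpp_logpost(spec, init))) break
    if (try == 20L) abort("could not find a finite starting point")
    init <- init * exp(rnorm(length(init), 0, 0.05)) +
      rnorm(length(init), 0, 0.05)
  }
  fit <- cpp_mcmc(spec, init, mcmc$n_burn, mcmc$n_keep, mcmc$thin,
                  mcmc$step, mcmc$adapt_interval)
  nm <- param_names(grid, variant)
  colnames(fit$draws) <- nm
  accept <- setNames(as.numeric(fit$accept), nm)
  if (variant != "dose_adjusted" && variant != "alternative2") {
    accept["gamma2"] <- NA_real_   # fixed at zero in these variants
  }
  structure(list(draws = fit$draws, accept = accept,
                 steps = setNames(as.numeric(fit$steps), nm),
                 variant = variant, grid = grid, hyper = hyper,
                 prior = prior, mcmc = mcmc, n_obs = nrow(data)),
            class = "dsd_posterior")
}

#' @export
print.dsd_posterior <- function(x, ...) {
  cat("<dsd_posterior> ", nrow(x$draws), " draws (", x$variant,
      " model), fitted to ", x$n_obs, " patients\n", sep = "")
  ar <- x$accept[is.finite(x$accept)]
  cat("  acceptance rates: ", sprintf("%.2f-%.2f", min(ar), max(ar)),
      " (Gibbs block for sigma_z_sq)\n", sep = "")
  invisible(x)
}

# Per-draw cell-level probabilities; rows = draws, one column per (j,k) or
# (j,k,M) in the order k (outer), j (inner), with subgroup blocks stacked.
posterior_cell_draws <- function(post) {
  grid <- post$grid; J <- grid$J; K <- grid$K
  dr <- post$draws
  d <- grid$scaled
  jk <- crossing(k = seq_len(K), j = seq_len(J))
  p <- sapply(seq_len(nrow(jk)), function(i) {
    expit(dr[, paste0("beta0_", jk$k[i])] + dr[, "beta1"] * d[jk$j[i]])
  })
  cells <- crossing(M = 0:1, k = seq_len(K), j = seq_len(J))
  if (post$variant == "alternative2") {
    q_list <- lapply(seq_len(nrow(cells)), function(i) {
      j <- cells$j[i]; k <- cells$k[i]; M <- cells$M[i]
      mu <- dr[, paste0("alpha_", k)] * exp(dr[, "delta"] * M) *
        (1 - exp(-dr[, "nu"] * d[j]))
      mt <- mu / post$prior$mu_scale
      eta <- dr[, "gamma_eff1"] * mt + dr[, "gamma_eff2"] * mt^2
      le0 <- expit(dr[, paste0("gamma0_l0_k", k, "_M", M)] + eta)
      le1 <- expit(dr[, paste0("gamma0_l1_k", k, "_M", M)] + eta)
      list(q2 = 1 - le1, qpos = 1 - le0)
    })
  } else {
    q_list <- lapply(seq_len(nrow(cells)), function(i) {
      z <- dr[, paste0("zeta_", cells$j[i], "_", cells$k[i], "_", cells$M[i])]
      list(q2 = expit(z), qpos = expit(dr[, "lambda"] + z))
    })
  }
  list(jk = jk, cells = cells, p = p,
       q2 = sapply(q_list, `[[`, "q2"),
       qpos = sapply(q_list, `[[`, "qpos"))
}

#' Posterior summaries per dose-schedule-subgroup cell
#'
#' Monte-Carlo posterior means of the efficacy category probabilities and
#' the toxicity probability, together with the tail probabilities used for
#' admissibility: `prob_safe = Pr(p(j,k) < phi_T | D)` and
#' `prob_eff = Pr(pi(j,k),M > phi_E | D)` (empirical draw fractions).
#'
#' @param post A [gibbs_sample()] fit.
#' @param phi_T,phi_E Toxicity upper / efficacy lower limits.
#' @return A tibble with one row per (dose, schedule, subgroup):
#'   `q1_hat`, `q2_hat`, `p_hat`, `prob_safe`, `prob_eff`.
#' @export
posterior_summaries <- function(post, phi_T = 0.3, phi_E = 0.3) {
  cd <- posterior_cell_draws(post)
  p_mean <- colMeans(cd$p)
  p_safe <- colMeans(cd$p < phi_T)
  jk_pos <- (cd$cells$k - 1L) * post$grid$J + cd$cells$j
  tibble(dose_index = cd$cells$j, schedule_index = cd$cells$k,
         subgroup = cd$cells$M,
         q1_hat = colMeans(cd$qpos - cd$q2),
         q2_hat = colMeans(cd$q2),
         p_hat = p_mean[jk_pos],
         prob_safe = p_safe[jk_pos],
         prob_eff = colMeans(cd$qpos > phi_E)) |>
    arrange(.data$subgroup, .data$schedule_index, .data$dose_index)
}

#' Stage-I Beta-Binomial safety probability
#'
#' Posterior probability that the toxicity rate of a combination is below
#' `phi_T` under the conjugate Beta-Binomial model used while data are
#' sparse: `p ~ Beta(kappa1 + m, kappa2 + n - m)` after observing `m` DLTs
#' in `n` patients. The default pseudo-counts (0.1, 0.2) let the observed
#' data dominate.
#'
#' @param m_tox Number of DLTs observed.
#' @param n_treated Number of patients treated.
#' @param phi_T Toxicity upper limit.
#' @param kappa1,kappa2 Beta prior pseudo-counts.
#' @return `Pr(p < phi_T | m, n)`.
#' @examples
#' beta_binomial_safety_prob(0, 3, 0.3)   # all clear: > 0.95
#' beta_binomial_safety_prob(3, 3, 0.3)   # all DLTs: < 0.05
#' @export
beta_binomial_safety_prob <- function(m_tox, n_treated, phi_T,
                                      kappa1 = 0.1, kappa2 = 0.2) {
  if (any(m_tox < 0) || any(n_treated < 0) || any(m_tox > n_treated)) {
    abort("need 0 <= m_tox <= n_treated")
  }
  check_prob(phi_T, "phi_T")
  pbeta(phi_T, kappa1 + m_tox, kappa2 + n_treated - m_tox)
}

ess_one <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(NA_real_)
  a <- as.numeric(acf(x, lag.max = min(100L, n - 2L), plot = FALSE)$acf)[-1]
  cut <- which(a < 0.05)
  L <- if (length(cut)) cut[1] - 1L else length(a)
  max(1, n / (1 + 2 * sum(a[seq_len(L)])))
}

split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2 || sd(x) == 0) return(NA_real_)
  h <- list(x[seq_len(n)], x[n + seq_len(n)])
  means <- vapply(h, mean, 0); vars <- vapply(h, var, 0)
  W <- mean(vars); B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' MCMC convergence diagnostics
#'
#' Effective sample size (initial-monotone autocorrelation truncation) and
#' split-chain convergence statistic per scalar parameter, with the
#' post-burn-in acceptance rate and warnings for acceptance outside
#' \[0.1, 0.6\] or degenerate (zero-variance) chains.
#'
#' @param post A [gibbs_sample()] fit.
#' @return A tibble (`parameter`, `mean`, `sd`, `ess`, `rhat`, `accept`,
#'   `warning`).
#' @export
mcmc_diagnostics <- function(post) {
  dr <- post$draws
  tibble(parameter = colnames(dr),
         mean = colMeans(dr),
         sd = apply(dr, 2, sd),
         ess = apply(dr, 2, ess_one),
         rhat = apply(dr, 2, split_rhat),
         accept = as.numeric(post$accept)) |>
    mutate(warning = dplyr::case_when(
      .data$sd == 0 ~ "zero-variance chain",
      is.finite(.data$accept) &
        (.data$accept < 0.1 | .data$accept > 0.6) ~ "acceptance outside [0.1, 0.6]",
      TRUE ~ NA_character_))
}

#' Export retained draws as a flat CSV
#'
#' One column per scalar parameter, one row per retained iteration, for
#' external diagnostic tooling.
#'
#' @param post A [gibbs_sample()] fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(post, path) {
  write.csv(as.data.frame(post$draws), path, row.names = FALSE)
  invisible(path)
}

#' Read patient records from CSV
#'
#' Flat file with columns `dose_index`, `schedule_index`, `subgroup`, `z`,
#' `x`, `y` (1-based indices, header required).
#'
#' @param path CSV file path.
#' @return A tibble of patient records.
#' @export
read_patient_records <- function(path) {
  dat <- as_tibble(read.csv(path))
  dat |> mutate(across(c("dose_index", "schedule_index", "subgroup", "x", "y"),
                       as.integer))
}

#' @rdname tidy.dsd_posterior
#' @export
tidy.dsd_posterior <- function(x, conf_level = 0.95, ...) {
  dr <- x$draws
  a <- (1 - conf_level) / 2
  tibble(term = colnames(dr),
         estimate = colMeans(dr),
         std.error = apply(dr, 2, sd),
         conf.low = apply(dr, 2, quantile, probs = a),
         conf.high = apply(dr, 2, quantile, probs = 1 - a))
}

#' Tidy and glance methods for posterior fits
#'
#' `tidy()` returns one row per scalar parameter with posterior mean, SD,
#' and equal-tailed credible interval; `glance()` a one-row model summary.
#'
#' @param x A `dsd_posterior`.
#' @param conf_level Credible-interval level.
#' @param ... Unused.
#' @name tidy.dsd_posterior
#' @export
glance.dsd_posterior <- function(x, ...) {
  diag <- mcmc_diagnostics(x)
  tibble(n_draws = nrow(x$draws), n_obs = x$n_obs, variant = x$variant,
         min_ess = min(diag$ess, na.rm = TRUE),
         max_rhat = max(diag$rhat, na.rm = TRUE),
         mean_accept = mean(x$accept, na.rm = TRUE))
}

#' Trace and density plot of selected parameters
#'
#' @param object A `dsd_posterior`.
#' @param pars Character vector of parameter names (default: the global
#'   scalars).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsd_posterior <- function(object, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- intersect(c("delta", "nu", "gamma", "lambda", "beta1",
                        "sigma_z_sq"), colnames(object$draws))
  }
  df <- as_tibble(object$draws[, pars, drop = FALSE]) |>
    mutate(iteration = row_number()) |>
    pivot_longer(-"iteration", names_to = "parameter")
  ggplot(df, aes(.data$iteration, .data$value)) +
    geom_line(linewidth = 0.2) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "retained iteration", y = NULL) +
    theme_bw()
}
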