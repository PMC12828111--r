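# Shared fixtures: all synthetic, generated in code at test time.

default_grid <- function() dose_grid(c(0.1, 0.5, 0.9), 3)

quick_mcmc <- function(seed = NULL) mcmc_config(n_burn = 200L, n_keep = 400L,
                                                seed = seed)

desk_mcmc <- function(seed = NULL) mcmc_config(n_burn = 500L, n_keep = 1000L,
                                               seed = seed)

# A representative ground-truth parameter state on the scaled-dose scale.
truth_state <- function() {
  zeta0 <- matrix(c(-1.5, -0.8, -0.6,
                    -1.2, -0.4, -0.3,
                    -1.0, -0.9, -0.8), nrow = 3)   # rows doses, cols schedules
  zeta <- array(0, c(3, 3, 2))
  zeta[, , 1] <- zeta0
  zeta[, , 2] <- zeta0 + 0.4
  parameter_state(
    immune_params(alpha = c(10, 20, 22), delta = 0.3, nu = 2.9,
                  sigma_z_sq = 4),
    toxicity_params(beta0 = c(-2.5, -2.2, -1.8), beta1 = 1.2),
    efficacy_params(zeta, gamma = 1.0, lambda = 1.5))
}

# Simulate n patients from the joint outcome model at a given state,
# uniformly allocated over the grid, subgroups Bernoulli(0.5).
simulate_from_model <- function(theta, grid, n) {
  j <- sample.int(grid$J, n, replace = TRUE)
  k <- sample.int(grid$K, n, replace = TRUE)
  M <- rbinom(n, 1, 0.5)
  mu <- mean_immune_response(theta$immune, grid, j, k, M)
  p <- toxicity_probability(theta$tox, grid, j, k)
  zeta <- theta$eff$zeta[cbind(j, k, M + 1L)]
  q <- efficacy_category_probs(zeta, theta$eff$lambda)
  u <- runif(n)
  y <- ifelse(u < q$q0, 0L, ifelse(u < q$q0 + q$q1, 1L, 2L))
  tibble::tibble(dose_index = j, schedule_index = k, subgroup = M,
                 z = rnorm(n, mu, sqrt(theta$immune$sigma_z_sq)),
                 x = rbinom(n, 1, p), y = y)
}

# Draw a fresh parameter state from the generative efficacy prior (dynamic
# chain) with the global truth values held fixed; used for calibrated
# parameter-recovery checks.
draw_state_from_efficacy_prior <- function(grid, hyper, prior, gamma,
                                           base = truth_state()) {
  J <- grid$J; K <- grid$K
  zeta <- array(0, c(J, K, 2))
  for (k in seq_len(K)) {
    zeta[1, k, 1] <- rnorm(1, hyper$zeta0[k], sqrt(hyper$tau_sq))
    for (j in seq_len(J)[-1]) {
      m <- efficacy_dynamic_prior_mean("proposed", zeta[j - 1, k, 1],
                                       base$immune, grid, gamma, j, k,
                                       mu_scale = prior$mu_scale)
      zeta[j, k, 1] <- rnorm(1, m, sqrt(hyper$sigma_e0_sq))
    }
    for (j in seq_len(J)) {
      repeat {
        z1 <- rnorm(1, zeta[j, k, 1], sqrt(hyper$sigma_e1_sq))
        if (z1 > zeta[j, k, 1]) break
      }
      zeta[j, k, 2] <- z1
    }
  }
  parameter_state(base$immune, base$tox,
                  efficacy_params(zeta, gamma = gamma,
                                  lambda = base$eff$lambda))
}

# A scenario in which every combination is overly toxic (p >= 0.55).
toxic_scenario <- function() {
  cells <- tidyr::crossing(subgroup = 0:1, schedule_index = 1:3,
                           dose_index = 1:3) |>
    dplyr::mutate(mu_z = 3 * dose_index + schedule_index,
                  p_tox = 0.55 + 0.05 * dose_index,
                  q2 = 0.2 + 0.1 * subgroup,
                  q1 = 0.3,
                  q0 = 1 - q1 - q2)
  scenario_truth(cells, doses = c(0.1, 0.5, 0.9), schedules = 3,
                 name = "synthetic-toxic")
}

# Build a posterior-summaries-shaped tibble from explicit per-cell values.
manual_summaries <- function(grid, prob_safe, prob_eff, q1 = 0.3, q2 = 0.2,
                             p = 0.1) {
  tidyr::crossing(subgroup = 0:1, schedule_index = seq_len(grid$K),
                  dose_index = seq_len(grid$J)) |>
    dplyr::mutate(q1_hat = q1, q2_hat = q2, p_hat = p,
                  prob_safe = prob_safe, prob_eff = prob_eff)
}

expect_combo_set_equal <- function(got, expected) {
  fmt <- function(df) sort(paste0(df$dose_index, ":", df$schedule_index))
  expect_identical(fmt(got), fmt(expected))
}
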