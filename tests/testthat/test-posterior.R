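# Beta-Binomial screening, Metropolis-within-Gibbs behaviour, posterior
# summaries, and diagnostics.

test_that("Beta-Binomial safety probabilities match numeric integration", {
  expect_equal(beta_binomial_safety_prob(0, 0, 1), 1)
  oracle <- function(a, b, cut) {
    stats::integrate(function(x) dbeta(x, a, b), 0, cut,
                     rel.tol = 1e-10)$value
  }
  p03 <- beta_binomial_safety_prob(0, 3, 0.3)
  expect_equal(p03, oracle(0.1, 3.2, 0.3), tolerance = 1e-7)
  expect_gt(p03, 0.95)
  p33 <- beta_binomial_safety_prob(3, 3, 0.3)
  expect_equal(p33, oracle(3.1, 0.2, 0.3), tolerance = 1e-7)
  expect_lt(p33, 0.05)    # fails the stage-I screen at c_i = 0.05
  expect_error(beta_binomial_safety_prob(4, 3, 0.3), "m_tox")
})

test_that("the sampler is deterministic given a seed and rejects bad input", {
  g <- default_grid()
  set.seed(31)
  dat <- simulate_from_model(truth_state(), g, 50)
  p1 <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 9))
  p2 <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 9))
  expect_identical(p1$draws, p2$draws)
  expect_error(gibbs_sample(dat[0, ], g, mcmc = quick_mcmc(1)), "empty")
  expect_error(mcmc_config(n_keep = 0), "n_keep")
})

test_that("every retained draw satisfies the hard parameter constraints", {
  g <- default_grid()
  set.seed(32)
  dat <- simulate_from_model(truth_state(), g, 80)
  post <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 2))
  dr <- post$draws
  expect_true(all(dr[, paste0("alpha_", 1:3)] > 0))
  expect_true(all(dr[, "delta"] > 0))
  expect_true(all(dr[, "nu"] > 0))
  expect_true(all(dr[, "gamma"] > 0))
  expect_true(all(dr[, "sigma_z_sq"] > 0))
  expect_true(all(dr[, "lambda"] > 0 & dr[, "lambda"] < 8))
  for (k in 1:3) for (j in 1:3) {
    expect_true(all(dr[, paste0("zeta_", j, "_", k, "_1")] >
                      dr[, paste0("zeta_", j, "_", k, "_0")]))
  }
})

test_that("posterior summaries are draw averages with coherent tail probabilities", {
  g <- default_grid()
  set.seed(33)
  dat <- simulate_from_model(truth_state(), g, 80)
  post <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 3))
  sums <- posterior_summaries(post, phi_T = 0.3, phi_E = 0.3)
  expect_identical(nrow(sums), 18L)
  expect_true(all(sums$q1_hat >= 0 & sums$q2_hat >= 0 &
                    sums$q1_hat + sums$q2_hat <= 1))
  expect_true(all(sums$prob_safe >= 0 & sums$prob_safe <= 1))
  # p_hat and prob_safe are shared across subgroups (toxicity has no M)
  wide <- sums |> dplyr::select(dose_index, schedule_index, subgroup, p_hat) |>
    tidyr::pivot_wider(names_from = subgroup, values_from = p_hat)
  expect_equal(wide$`0`, wide$`1`)
  # recompute one cell's tail probability straight from the draws
  p22 <- plogis(post$draws[, "beta0_2"] + post$draws[, "beta1"] * g$scaled[2])
  expect_equal(sums$prob_safe[sums$dose_index == 2 & sums$schedule_index == 2 &
                                sums$subgroup == 0],
               mean(p22 < 0.3))
  # a tail cutoff everything satisfies gives probability one
  sums_loose <- posterior_summaries(post, phi_T = 1 - 1e-12, phi_E = 1e-12)
  expect_true(all(sums_loose$prob_safe == 1))
  expect_true(all(sums_loose$prob_eff == 1))
})

test_that("posterior means recover the generating parameters on rich data", {
  g <- default_grid()
  set.seed(34)
  theta <- truth_state()
  dat <- simulate_from_model(theta, g, 600)
  post <- gibbs_sample(dat, g, mcmc = desk_mcmc(seed = 4))
  td <- tidy(post)
  for (par in c(nu = "nu", delta = "delta", lambda = "lambda")) {
    truthv <- switch(par, nu = theta$immune$nu, delta = theta$immune$delta,
                     lambda = theta$eff$lambda)
    row <- td[td$term == par, ]
    expect_lt(abs(row$estimate - truthv), 3 * row$std.error + 1e-9)
  }
})

test_that("prior-only sampling reproduces the stated prior tail facts", {
  g <- default_grid()
  post <- gibbs_sample(NULL, g, mcmc = mcmc_config(1000, 4000, seed = 5),
                       prior_only = TRUE)
  dr <- post$draws
  # no-dose toxicity: Pr(expit(beta0) < 0.12) = 0.975 under N(-4, 1)
  expect_equal(mean(plogis(dr[, "beta0_1"]) < 0.12), 0.975, tolerance = 0.02)
  # delta marginal keeps its prior mean log(1.5) (heavy-tailed: wide box)
  expect_lt(abs(mean(dr[, "delta"]) - log(1.5)), 0.3)
  # lambda uniform on (0, 8)
  expect_equal(mean(dr[, "lambda"]), 4, tolerance = 0.5)
  expect_true(all(dr[, "lambda"] > 0 & dr[, "lambda"] < 8))
  # truncation respected in the prior too
  expect_true(all(dr[, "zeta_2_2_1"] > dr[, "zeta_2_2_0"]))
})

test_that("the immune-response-free variant ignores the z values", {
  g <- default_grid()
  set.seed(36)
  dat <- simulate_from_model(truth_state(), g, 60)
  p1 <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 8),
                     variant = "alternative1")
  dat2 <- dat
  dat2$z <- sample(dat2$z) * 100
  p2 <- gibbs_sample(dat2, g, mcmc = quick_mcmc(seed = 8),
                     variant = "alternative1")
  eff_cols <- grep("zeta|lambda|gamma$|beta", colnames(p1$draws))
  expect_identical(p1$draws[, eff_cols], p2$draws[, eff_cols])
})

test_that("the proportional-odds comparator fits and keeps its orderings", {
  g <- default_grid()
  set.seed(37)
  dat <- simulate_from_model(truth_state(), g, 80)
  post <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 10),
                       variant = "alternative2")
  dr <- post$draws
  for (k in 1:3) for (M in 0:1) {
    expect_true(all(dr[, paste0("gamma0_l0_k", k, "_M", M)] <
                      dr[, paste0("gamma0_l1_k", k, "_M", M)]))
  }
  for (k in 1:3) for (l in 0:1) {
    expect_true(all(dr[, paste0("gamma0_l", l, "_k", k, "_M0")] >
                      dr[, paste0("gamma0_l", l, "_k", k, "_M1")]))
  }
  sums <- posterior_summaries(post)
  expect_true(all(sums$q1_hat >= 0 & sums$q1_hat + sums$q2_hat <= 1))
})

test_that("diagnostics flag degenerate chains and cover every scalar", {
  g <- default_grid()
  set.seed(38)
  dat <- simulate_from_model(truth_state(), g, 50)
  post <- gibbs_sample(dat, g, mcmc = quick_mcmc(seed = 12))
  diag <- mcmc_diagnostics(post)
  expect_identical(diag$parameter, colnames(post$draws))
  # near-independent draws have split-Rhat close to 1
  fake <- post
  set.seed(1)
  fake$draws <- matrix(rnorm(400 * ncol(post$draws)), nrow = 400,
                       dimnames = list(NULL, colnames(post$draws)))
  d2 <- mcmc_diagnostics(fake)
  expect_true(all(abs(d2$rhat - 1) < 0.08, na.rm = TRUE))
  # constant chain yields a zero-variance warning
  fake$draws[, "nu"] <- 1
  d3 <- mcmc_diagnostics(fake)
  expect_identical(d3$warning[d3$parameter == "nu"], "zero-variance chain")
})
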