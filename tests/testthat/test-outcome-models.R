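# Dose standardization, plateau immune-response model, logistic toxicity,
# and the ordinal efficacy transforms.

test_that("dose standardization matches direct arithmetic and fixes dispersion", {
  raw <- c(0.1, 0.5, 0.9)
  oracle <- raw * 0.5 / sqrt(mean((raw - mean(raw))^2))
  expect_equal(standardize_doses(raw), oracle, tolerance = 1e-12)
  expect_equal(standardize_doses(raw), c(0.15309, 0.76546, 1.37783),
               tolerance = 1e-4)
  # {1, 2} already has population dispersion 0.5, so scaling is the identity
  expect_equal(standardize_doses(c(1, 2)), c(1, 2))
  set.seed(4)
  for (i in 1:10) {
    g <- sort(runif(sample(2:6, 1), 0.01, 5))
    s <- standardize_doses(g)
    expect_equal(sqrt(mean((s - mean(s))^2)), 0.5, tolerance = 1e-9)
  }
  expect_error(standardize_doses(c(2, 1)), "increasing")
  expect_error(standardize_doses(3), "at least two")
})

test_that("plateau model vanishes at zero dose, saturates, and factorizes by subgroup", {
  ip <- immune_params(alpha = 10, delta = 0.4, nu = 4.46, sigma_z_sq = 1)
  g <- dose_grid(c(1e-9, 0.5, 0.9), 1)
  expect_equal(mean_immune_response(ip, g, 1, 1, 0, dose_scale = "raw"), 0,
               tolerance = 1e-7)
  # published scenario-1 (d2,s1,M=0) value 8.9 arises at alpha=10, nu=4.46
  val <- mean_immune_response(ip, g, 2, 1, 0, dose_scale = "raw")
  expect_equal(val, 10 * (1 - exp(-4.46 * 0.5)), tolerance = 1e-12)
  expect_equal(round(val, 1), 8.9)
  # marker-positive/negative ratio is exp(delta) at every combination
  g3 <- default_grid()
  ip3 <- immune_params(alpha = c(5, 10, 20), delta = 0.4, nu = 2)
  for (j in 1:3) for (k in 1:3) {
    expect_equal(mean_immune_response(ip3, g3, j, k, 1) /
                   mean_immune_response(ip3, g3, j, k, 0), exp(0.4))
  }
  # strictly increasing in dose, bounded by the plateau
  mus <- mean_immune_response(ip3, g3, 1:3, 2, 0)
  expect_true(all(diff(mus) > 0))
  expect_true(all(mus < ip3$alpha[2]))
})

test_that("logistic toxicity model gives 1.8% at the prior-centered intercept", {
  g <- default_grid()
  tp <- toxicity_params(beta0 = rep(-4, 3), beta1 = 0)
  expect_equal(round(toxicity_probability(tp, g, 1, 1), 3), 0.018)
  # flat in dose when the slope is zero; 0.5 at the logit origin
  expect_equal(toxicity_probability(tp, g, 1, 2),
               toxicity_probability(tp, g, 3, 2))
  expect_equal(toxicity_probability(toxicity_params(rep(0, 3), 0), g, 2, 2),
               0.5)
})

test_that("efficacy category probabilities form a simplex with the stated limits", {
  # lambda -> 0: no SD mass, q0 = q2 = 1/2 at zeta = 0
  q <- efficacy_category_probs(0, lambda = 1e-12)
  expect_equal(unlist(q), c(q0 = 0.5, q1 = 0, q2 = 0.5), tolerance = 1e-9)
  # the uniform lambda prior spans Pr(Y > 0) up to 0.99 when Pr(Y = 2) = 0.03
  q <- efficacy_category_probs(qlogis(0.03), lambda = 8)
  expect_equal(round(q$q1 + q$q2, 2), 0.99)
  set.seed(11)
  zs <- rnorm(200, 0, 3); ls <- runif(200, 0, 8)
  qq <- efficacy_category_probs(zs, ls)
  expect_true(all(abs(qq$q0 + qq$q1 + qq$q2 - 1) < 1e-12))
  expect_true(all(qq$q1 >= 0))
})

test_that("dynamic prior mean tracks the immune-response increment", {
  g <- dose_grid(c(0.1, 0.5, 0.9), 1)
  ip <- immune_params(alpha = 10, delta = 0.3, nu = 4.46)
  # gamma = 0: pure random walk centered at the previous dose
  expect_equal(efficacy_dynamic_prior_mean("proposed", -1.1, ip, g, 0, 2, 1,
                                           mu_scale = 1, dose_scale = "raw"),
               -1.1)
  # plateaued immune response (huge nu): zero increment
  ip_flat <- immune_params(alpha = 10, delta = 0.3, nu = 500)
  expect_equal(efficacy_dynamic_prior_mean("proposed", 0.2, ip_flat, g, 1, 3, 1,
                                           mu_scale = 1, dose_scale = "raw"),
               0.2, tolerance = 1e-9)
  # unscaled increment for d 0.1 -> 0.5: 10 (e^{-0.446} - e^{-2.23})
  expect_equal(efficacy_dynamic_prior_mean("proposed", 0, ip, g, 1, 2, 1,
                                           mu_scale = 1, dose_scale = "raw"),
               10 * (exp(-0.446) - exp(-2.23)), tolerance = 1e-12)
  expect_equal(round(efficacy_dynamic_prior_mean("proposed", 0, ip, g, 1, 2, 1,
                                                 mu_scale = 1,
                                                 dose_scale = "raw"), 2),
               5.33)
  # the immune-response-free comparator walks on dose increments instead
  expect_equal(efficacy_dynamic_prior_mean("alternative1", 1, ip, g, 2, 2, 1,
                                           dose_scale = "raw"),
               1 + 2 * 0.4)
  expect_error(efficacy_dynamic_prior_mean("proposed", 0, ip, g, 1, 1, 1),
               "j >= 2")
})

test_that("proportional-odds comparator honours its cut-point structure", {
  # no regression effect: categories split at the intercepts
  q <- alt2_efficacy_probs(c(0, 30), gamma1 = 0, gamma2 = 0, mu_z = 1)
  expect_equal(unlist(q), c(q0 = 0.5, q1 = 0.5, q2 = 0), tolerance = 1e-9)
  # cumulative probabilities move monotonically with the covariate
  qa <- alt2_efficacy_probs(c(-1, 1), 1, 0, mu_z = 0)
  qb <- alt2_efficacy_probs(c(-1, 1), 1, 0, mu_z = 2)
  expect_true(qb$q0 > qa$q0)                 # Pr(Y <= 0) rises with eta
  expect_true(qb$q0 + qb$q1 > qa$q0 + qa$q1)
  # a downward subgroup shift of both intercepts raises response rates
  qneg <- alt2_efficacy_probs(c(-0.5, 0.5), -1, 0, mu_z = 1)
  qpos <- alt2_efficacy_probs(c(-1.0, 0.0), -1, 0, mu_z = 1)
  expect_true(qpos$q2 > qneg$q2)
  expect_error(alt2_efficacy_probs(c(1, 0), 0, 0, 1), "increasing")
})
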