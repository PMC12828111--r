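# Utility function, admissibility, adaptive randomization, stage-I
# escalation, and final selection.

test_that("utility reproduces published values and is monotone", {
  w <- utility_weights()
  expect_equal(utility(0, 0, 0, w), 0)
  expect_equal(utility(0.452, 0.248, 0.18, w), 0.42, tolerance = 1e-9)
  expect_equal(utility(0.432, 0.168, 0.48, w), -0.96, tolerance = 1e-9)
  # nonincreasing in p under both conventions; increasing in q2
  wp <- utility_weights(penalty = "proportional")
  ps <- seq(0, 0.9, by = 0.05)
  for (ww in list(w, wp)) {
    u <- utility(0.3, 0.2, ps, ww)
    expect_true(all(diff(u) <= 1e-12))
  }
  expect_true(all(diff(utility(0.1, seq(0, 0.9, 0.1), 0.1, w)) > 0))
  # the fixed penalty drops utility by exactly w3 across the threshold
  expect_equal(utility(0.3, 0.2, 0.3 - 1e-9, w) -
                 utility(0.3, 0.2, 0.3 + 1e-9, w),
               1.2, tolerance = 1e-6)
  expect_error(utility(0.8, 0.5, 0.1, w), "q1 \\+ q2")
})

test_that("plug-in utilities evaluate the penalty at the posterior mean", {
  g <- default_grid()
  sums <- manual_summaries(g, prob_safe = 1, prob_eff = 1,
                           q1 = 0.4, q2 = 0.3, p = 0.1)
  eu <- estimated_utilities(sums)
  expect_identical(nrow(eu), 18L)
  expect_equal(unique(eu$utility), 0.3 + 0.5 * 0.4 - 0.3 * 0.1)
  eu_hot <- estimated_utilities(manual_summaries(g, 1, 1, 0.4, 0.3, 0.31))
  expect_equal(unique(eu_hot$utility),
               0.3 + 0.5 * 0.4 - 0.3 * 0.31 - 1.2)
})

test_that("stage I starts every schedule at its lowest dose and screens before escalating", {
  cfg <- design_config(mcmc = quick_mcmc())
  st <- stage1_init(cfg)
  # first pass: (1,1), (1,2), (1,3)
  for (k in 1:3) {
    dec <- stage1_step(st, cfg)
    expect_false(dec$complete)
    expect_identical(c(dec$dose_index, dec$schedule_index), c(1L, k))
    st <- stage1_record(dec$state, dec$dose_index, dec$schedule_index, 3L, 0L)
  }
  # no toxicity anywhere: full escalation, nine cohorts, then completion
  n_cohorts <- 3L
  repeat {
    dec <- stage1_step(st, cfg)
    if (dec$complete) { st <- dec$state; break }
    expect_identical(dec$dose_index, dec$state$h[dec$schedule_index] + 1L)
    st <- stage1_record(dec$state, dec$dose_index, dec$schedule_index, 3L, 0L)
    n_cohorts <- n_cohorts + 1L
  }
  expect_identical(n_cohorts, 9L)
  expect_identical(st$h, rep(3L, 3))
  expect_error(stage1_step(st, cfg), "complete")
})

test_that("a fully toxic first cohort closes its schedule at the lowest dose", {
  cfg <- design_config(mcmc = quick_mcmc())
  st <- stage1_init(cfg)
  dec <- stage1_step(st, cfg)
  st <- stage1_record(dec$state, 1L, 1L, 3L, 3L)  # 3/3 DLTs on schedule 1
  # skip through the other schedules first cohorts
  for (k in 2:3) {
    dec <- stage1_step(st, cfg)
    st <- stage1_record(dec$state, dec$dose_index, dec$schedule_index, 3L, 0L)
  }
  dec <- stage1_step(st, cfg)   # schedule 1's turn: must close, move on
  expect_false(dec$state$open[1])
  expect_identical(dec$schedule_index, 2L)
  expect_identical(dec$dose_index, 2L)
})

test_that("admissibility uses strict posterior cutoffs", {
  cfg <- design_config(mcmc = quick_mcmc())
  g <- cfg$grid
  expect_identical(nrow(admissible_set(manual_summaries(g, 1, 1), cfg)), 18L)
  expect_identical(nrow(admissible_set(manual_summaries(g, 0, 1), cfg)), 0L)
  # boundary equality is excluded (strict inequality in both requirements)
  expect_identical(nrow(admissible_set(manual_summaries(g, 0.2, 1), cfg)), 0L)
  expect_identical(nrow(admissible_set(manual_summaries(g, 1, 0.2), cfg)), 0L)
})

test_that("randomization probabilities are proportional, floored, and normalized", {
  tb <- tibble::tibble(dose_index = 1:2, schedule_index = 1L,
                       utility = c(0.4, 0.4))
  expect_equal(randomization_probabilities(tb)$psi, c(0.5, 0.5))
  tb$utility <- c(0.3, 0.1)
  expect_equal(randomization_probabilities(tb)$psi, c(0.75, 0.25))
  tb$utility <- c(0.3, -0.2)
  expect_equal(randomization_probabilities(tb, floor = 0.01)$psi,
               c(30 / 31, 1 / 31))
  expect_error(randomization_probabilities(tb[0, ]), "empty")
  # support is exactly the admissible set and always sums to one
  set.seed(44)
  for (i in 1:20) {
    n <- sample(1:9, 1)
    tb <- tibble::tibble(dose_index = seq_len(n), schedule_index = 1L,
                         utility = runif(n, -1, 1))
    psi <- randomization_probabilities(tb, floor = 0.01)$psi
    expect_equal(sum(psi), 1)
    expect_true(all(psi > 0))
  }
})

test_that("final selection takes the utility argmax with deterministic ties", {
  cfg <- design_config(mcmc = quick_mcmc())
  g <- cfg$grid
  sums <- manual_summaries(g, 1, 1, q1 = 0.2, q2 = 0.1, p = 0.05) |>
    dplyr::mutate(q2_hat = dplyr::if_else(dose_index == 2 &
                                            schedule_index == 2, 0.6, q2_hat))
  sel <- select_final(sums, cfg, 0)
  expect_identical(c(sel$dose_index, sel$schedule_index), c(2L, 2L))
  # empty admissible set: no acceptable dose
  expect_null(select_final(manual_summaries(g, 0, 0), cfg, 1))
  # exact tie resolves to the lowest dose, then lowest schedule
  tied <- manual_summaries(g, 1, 1, q1 = 0.2, q2 = 0.1, p = 0.05)
  sel <- select_final(tied, cfg, 0)
  expect_identical(c(sel$dose_index, sel$schedule_index), c(1L, 1L))
})

test_that("design configuration rejects invalid cutoffs and sizes", {
  expect_error(design_config(c_i = 0), "strictly inside")
  expect_error(design_config(n_max = 2, cohort_size = 3), "cohort_size")
  expect_error(design_config(prevalence = 1.4), "probability")
})
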