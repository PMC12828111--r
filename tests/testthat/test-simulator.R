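# Copula machinery, outcome generation, whole-trial simulation, and
# operating-characteristic aggregation.

test_that("Gumbel copula CDF matches the closed form and its boundaries", {
  # independence at theta = 1
  expect_equal(gumbel_copula_cdf(0.3, 0.7, 1), 0.21, tolerance = 1e-12)
  # closed-form arithmetic oracle at theta = 1.5
  oracle <- exp(-((-log(0.5))^1.5 + (-log(0.5))^1.5)^(1 / 1.5))
  expect_equal(gumbel_copula_cdf(0.5, 0.5, 1.5), oracle, tolerance = 1e-12)
  # uniform margins
  vs <- c(0, 0.25, 0.8, 1)
  expect_equal(gumbel_copula_cdf(rep(1, 4), vs, 2), vs)
  expect_equal(gumbel_copula_cdf(vs, rep(1, 4), 2), vs)
  expect_equal(gumbel_copula_cdf(0, 0.4, 1.7), 0)
  expect_error(gumbel_copula_cdf(0.5, 0.5, 0.8), "theta")
})

test_that("discrete joint outcome tables reproduce their margins exactly", {
  # independence factorizes
  tab <- discrete_joint_outcomes(0.5, c(0.2, 0.3, 0.5), 1)
  expect_equal(tab["x1", "y2"], 0.25, tolerance = 1e-12)
  expect_equal(as.vector(tab), as.vector(outer(c(0.5, 0.5),
                                               c(0.2, 0.3, 0.5))),
               tolerance = 1e-12)
  # the non-toxic no-response cell is the copula CDF at the cut-points
  tab <- discrete_joint_outcomes(0.5, c(0.5, 0, 0.5), 1.5)
  expect_equal(tab["x0", "y0"], gumbel_copula_cdf(0.5, 0.5, 1.5),
               tolerance = 1e-12)
  # margins are exact across a grid of margins and dependence strengths
  for (p in c(0.05, 0.3, 0.65)) {
    for (theta in c(1, 1.2, 1.5, 2.5)) {
      for (q in list(c(0.2, 0.3, 0.5), c(0.7, 0.2, 0.1), c(1/3, 1/3, 1/3))) {
        tab <- discrete_joint_outcomes(p, q, theta)
        expect_true(all(tab >= 0))
        expect_equal(sum(tab), 1, tolerance = 1e-12)
        expect_equal(unname(rowSums(tab)), c(1 - p, p), tolerance = 1e-12)
        expect_equal(unname(colSums(tab)), q, tolerance = 1e-12)
      }
    }
  }
})

test_that("generated patients follow the scenario margins", {
  s <- load_builtin_scenario(1)
  cell <- s$cells |>
    dplyr::filter(dose_index == 2, schedule_index == 2, subgroup == 0)
  set.seed(55)
  n <- 10000
  draws <- purrr::map(seq_len(n), ~ generate_patient(s, 2, 2, 0)) |>
    purrr::list_rbind()
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(draws$x) - cell$p_tox), 3 * se(cell$p_tox))
  expect_lt(abs(mean(draws$y > 0) - cell$pi), 3 * se(cell$pi))
  expect_lt(abs(mean(draws$z) - cell$mu_z), 3 * s$sigma_z / sqrt(n))
  # degenerate immune noise pins z at the cell mean
  s0 <- s; s0$sigma_z <- 1e-9
  expect_equal(generate_patient(s0, 1, 3, 1)$z,
               s$cells$mu_z[s$cells$dose_index == 1 &
                              s$cells$schedule_index == 3 &
                              s$cells$subgroup == 1],
               tolerance = 1e-6)
})

test_that("a whole trial is reproducible, bounded, and honours stage-I ordering", {
  s <- load_builtin_scenario(4)
  cfg <- design_config(n_max = 45, mcmc = mcmc_config(150, 300))
  t1 <- run_trial(s, cfg, seed = 71)
  t2 <- run_trial(s, cfg, seed = 71)
  expect_identical(t1$selection, t2$selection)
  expect_identical(t1$counts, t2$counts)
  expect_lte(t1$n_enrolled, cfg$n_max)
  expect_identical(sum(t1$counts$n_treated), t1$n_enrolled)
  # stage-I escalation never skips a dose within a schedule
  s1 <- purrr::keep(t1$trace, ~ .x$stage == 1L)
  seen <- matrix(FALSE, 3, 3)
  for (rec in s1) {
    j <- rec$dose_index; k <- rec$schedule_index
    if (j > 1) expect_true(seen[j - 1, k])
    seen[j, k] <- TRUE
  }
  # stage-II assignments stay inside the interim admissible sets
  for (rec in purrr::keep(t1$trace, ~ .x$stage == 2L)) {
    adm_keys <- paste(rec$admissible$subgroup, rec$admissible$dose_index,
                      rec$admissible$schedule_index)
    asg_keys <- paste(rec$assignments$subgroup, rec$assignments$dose_index,
                      rec$assignments$schedule_index)
    expect_true(all(asg_keys %in% adm_keys))
  }
})

test_that("operating characteristics aggregate replicate trials coherently", {
  s <- load_builtin_scenario(1)
  cfg <- design_config(n_max = 36, mcmc = mcmc_config(150, 300))
  oc <- operating_characteristics(s, cfg, n_reps = 2, seed = 13)
  # selection percentages plus percent-none partition each subgroup
  tot <- oc$cells |>
    dplyr::group_by(subgroup) |>
    dplyr::summarise(sel = sum(sel_pct)) |>
    dplyr::left_join(oc$none, by = "subgroup")
  expect_equal(tot$sel + tot$pct_none, c(100, 100))
  # a single replicate reduces to that trial's one-hot selection and counts
  oc1 <- operating_characteristics(s, cfg, n_reps = 1, seed = 13)
  tr <- run_trial(s, cfg, seed = dosesched:::replicate_seeds(13, 1))
  expect_equal(oc1$mean_sample_size, tr$n_enrolled)
  joined <- oc1$cells |>
    dplyr::left_join(tr$counts, by = c("dose_index", "schedule_index",
                                       "subgroup"))
  expect_equal(joined$mean_n, as.numeric(joined$n_treated))
  sel_cells <- oc1$cells |> dplyr::filter(sel_pct > 0)
  expect_lte(nrow(sel_cells), 2L)
})

test_that("trial traces serialize to JSON lines", {
  s <- load_builtin_scenario(1)
  cfg <- design_config(n_max = 30, mcmc = mcmc_config(100, 200))
  tr <- run_trial(s, cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trial_trace(tr, path)
  lines <- readLines(path)
  expect_identical(length(lines), length(tr$trace))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$stage, 1L)
})

test_that("tidiers and plots return the documented shapes", {
  s <- load_builtin_scenario(1)
  cfg <- design_config(n_max = 30, mcmc = mcmc_config(100, 200))
  tr <- run_trial(s, cfg, seed = 6)
  td <- tidy(tr)
  expect_identical(nrow(td), 18L)
  expect_true(is.logical(td$selected))
  gl <- glance(tr)
  expect_identical(nrow(gl), 1L)
  oc <- operating_characteristics(s, cfg, n_reps = 1, seed = 2)
  expect_s3_class(autoplot(oc), "ggplot")
  expect_s3_class(plot_scenario(s), "ggplot")
  set.seed(1)
  post <- gibbs_sample(simulate_from_model(truth_state(), cfg$grid, 40),
                       cfg$grid, mcmc = quick_mcmc(seed = 3))
  expect_s3_class(autoplot(post), "ggplot")
  expect_identical(nrow(glance(post)), 1L)
})
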