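#' Gumbel copula CDF
#'
#' `C(u, v) = exp(-[(-log u)^theta + (-log v)^theta]^(1/theta))` with
#' `theta >= 1`; `theta = 1` is the independence copula, larger `theta`
#' induces stronger positive dependence.
#'
#' @param u,v Uniform margins in \[0, 1\].
#' @param theta Dependence parameter (>= 1).
#' @return The joint CDF value(s).
#' @export
gumbel_copula_cdf <- function(u, v, theta) {
  if (any(theta < 1)) abort("`theta` must be >= 1")
  u <- check_prob(u, "u"); v <- check_prob(v, "v")
  # the closed form already honours the boundaries: C(0, .) = 0 via the
  # infinite exponent sum, and C(1, v) = v since (-log 1)^theta = 0
  exp(-((-log(u))^theta + (-log(v))^theta)^(1 / theta))
}

#' Exact joint toxicity-efficacy table from the Gumbel copula
#'
#' Discretizes a Gumbel-copula pair `(u, v)` into the binary DLT outcome
#' `X` and ordinal efficacy `Y`: the non-toxic event occupies the lower
#' `u`-tail (`X = 0` iff `u <= 1 - p`) and efficacy categories cut the
#' `v`-margin at `q0` and `q0 + q1` (`Y = 0` for `v <= q0`, etc.), so
#' `Pr(X = 0, Y <= l)` is the copula CDF evaluated at the cut-points and
#' all cell probabilities follow by differencing. Margins are reproduced
#' exactly; with `theta = 1.5` toxicity is positively associated with
#' better response, consistent with immune activation driving both.
#'
#' @param p Toxicity probability.
#' @param q Numeric vector `(q0, q1, q2)` of efficacy category
#'   probabilities (sums to 1).
#' @param theta Gumbel dependence parameter (>= 1).
#' @return A 2 x 3 matrix `Pr(X = x, Y = y)` with rownames `x0`, `x1` and
#'   colnames `y0`, `y1`, `y2`.
#' @examples
#' discrete_joint_outcomes(0.5, c(0.2, 0.3, 0.5), theta = 1)
#' @export
discrete_joint_outcomes <- function(p, q, theta) {
  p <- check_prob(p, "p")
  if (length(q) != 3L || abs(sum(q) - 1) > 1e-9) {
    abort("`q` must be (q0, q1, q2) summing to 1")
  }
  q <- check_prob(q, "q")
  c0 <- gumbel_copula_cdf(1 - p, q[1], theta)
  c1 <- gumbel_copula_cdf(1 - p, q[1] + q[2], theta)
  x0 <- c(c0, c1 - c0, (1 - p) - c1)
  x1 <- c(q[1] - c0, q[2] - (c1 - c0), p - q[1] - q[2] + c1)
  out <- rbind(x0 = pmax(x0, 0), x1 = pmax(x1, 0))
  colnames(out) <- paste0("y", 0:2)
  out
}

#' Simulate one patient outcome from a truth scenario
#'
#' Draws the immune response `Z ~ N(mu_z, sigma_z^2)` and the correlated
#' pair `(X, Y)` from the exact Gumbel-copula cell probabilities of
#' [discrete_joint_outcomes()], using the current R RNG stream.
#'
#' @param s A `dsd_scenario`.
#' @param j,k Dose and schedule index.
#' @param M Subgroup indicator.
#' @return A one-row tibble (`dose_index`, `schedule_index`, `subgroup`,
#'   `z`, `x`, `y`).
#' @export
generate_patient <- function(s, j, k, M) {
  cell <- s$cells |>
    filter(.data$dose_index == j, .data$schedule_index == k,
           .data$subgroup == M)
  if (nrow(cell) != 1L) abort("unknown scenario cell")
  tab <- discrete_joint_outcomes(cell$p_tox, c(cell$q0, cell$q1, cell$q2),
                                 s$copula_theta)
  pick <- sample.int(6L, 1L, prob = as.vector(tab))
  # column-major order of the 2 x 3 table: (x0,y0), (x1,y0), (x0,y1), ...
  x <- (pick - 1L) %% 2L
  y <- (pick - 1L) %/% 2L
  tibble(dose_index = as.integer(j), schedule_index = as.integer(k),
         subgroup = as.integer(M),
         z = rnorm(1, cell$mu_z, s$sigma_z), x = x, y = y)
}

draw_subgroup <- function(prevalence) {
  as.integer(runif(1) < prevalence)
}

#' Simulate one complete trial
#'
#' Runs the two-stage design against a truth scenario: stage I round-robin
#' toxicity-screened escalation per schedule (Beta-Binomial screen at
#' `c_i`), then stage II model-based allocation — per cohort the posterior
#' is refit on all accrued data, admissible sets are formed per subgroup,
#' and each enrolled patient is adaptively randomized within their subgroup
#' with probability proportional to the floored posterior-mean utility. A
#' subgroup whose admissible set empties is closed (its future arrivals go
#' off protocol); the trial terminates early when both subgroups close. At
#' the maximum sample size the posterior is refit once more and the
#' admissible combination with the largest posterior-mean utility is
#' selected per subgroup.
#'
#' @param s A `dsd_scenario`.
#' @param cfg A [design_config()] with a grid matching the scenario.
#' @param seed Integer seed making the whole trial reproducible.
#' @return An object of class `dsd_trial`: `selection` (one row per
#'   subgroup; `NA` indices mean no acceptable dose), `counts` (patients
#'   per dose-schedule-subgroup), `n_enrolled`, `early_stop`, `trace`
#'   (per-cohort decision records), `seed`.
#' @export
run_trial <- function(s, cfg, seed = 1L) {
  if (s$grid$J != cfg$grid$J || s$grid$K != cfg$grid$K ||
      !isTRUE(all.equal(s$grid$raw, cfg$grid$raw))) {
    abort("scenario and design config use different dose-schedule grids")
  }
  set.seed(as.integer(seed))
  grid <- cfg$grid
  data <- tibble(dose_index = integer(), schedule_index = integer(),
                 subgroup = integer(), z = numeric(), x = integer(),
                 y = integer())
  trace <- list()

  # ---- stage I: schedule-wise escalation on toxicity only ----
  st <- stage1_init(cfg)
  repeat {
    if (nrow(data) >= cfg$n_max) break
    dec <- stage1_step(st, cfg)
    st <- dec$state
    if (dec$complete) break
    n_c <- min(cfg$cohort_size, cfg$n_max - nrow(data))
    cohort <- purrr::map(seq_len(n_c), function(i) {
      generate_patient(s, dec$dose_index, dec$schedule_index,
                       draw_subgroup(cfg$prevalence))
    }) |> list_rbind()
    data <- bind_rows(data, cohort)
    st <- stage1_record(st, dec$dose_index, dec$schedule_index,
                        nrow(cohort), sum(cohort$x))
    trace[[length(trace) + 1L]] <- list(
      stage = 1L, n = nrow(data), dose_index = dec$dose_index,
      schedule_index = dec$schedule_index, n_tox = sum(cohort$x))
  }

  # ---- stage II: utility-guided adaptive randomization ----
  open <- c(`0` = TRUE, `1` = TRUE)
  early_stop <- FALSE
  final_summaries <- NULL
  while (nrow(data) < cfg$n_max) {
    post <- gibbs_sample(data, grid, cfg$hyper, cfg$prior, cfg$mcmc,
                         variant = cfg$variant)
    sums <- posterior_summaries(post, cfg$phi_T, cfg$phi_E)
    final_summaries <- sums
    adm <- admissible_set(sums, cfg)
    psi <- list()
    for (M in subgroup_levels()) {
      key <- as.character(M)
      if (!open[[key]]) next
      adm_m <- adm |> filter(.data$subgroup == M)
      if (nrow(adm_m) == 0L) {
        open[[key]] <- FALSE       # conclude: no acceptable dose for M
        next
      }
      psi[[key]] <- adm_m |>
        estimated_utilities(cfg$weights) |>
        randomization_probabilities(cfg$rand_floor)
    }
    if (!any(unlist(open))) {
      early_stop <- TRUE
      break
    }
    n_c <- min(cfg$cohort_size, cfg$n_max - nrow(data))
    cohort <- list()
    while (length(cohort) < n_c) {
      M <- draw_subgroup(cfg$prevalence)
      if (!open[[as.character(M)]]) next   # off protocol, not enrolled
      w <- psi[[as.character(M)]]
      pick <- sample.int(nrow(w), 1L, prob = w$psi)
      cohort[[length(cohort) + 1L]] <-
        generate_patient(s, w$dose_index[pick], w$schedule_index[pick], M)
    }
    cohort <- list_rbind(cohort)
    data <- bind_rows(data, cohort)
    trace[[length(trace) + 1L]] <- list(
      stage = 2L, n = nrow(data),
      admissible = adm |> select("subgroup", "dose_index", "schedule_index"),
      psi = purrr::map(psi, ~ .x |> select("dose_index", "schedule_index",
                                           "psi")),
      assignments = cohort |> select("dose_index", "schedule_index",
                                     "subgroup"))
  }

  # ---- final analysis ----
  selection <- tibble(subgroup = subgroup_levels(),
                      dose_index = NA_integer_, schedule_index = NA_integer_)
  if (!early_stop) {
    post <- gibbs_sample(data, grid, cfg$hyper, cfg$prior, cfg$mcmc,
                         variant = cfg$variant)
    sums <- posterior_summaries(post, cfg$phi_T, cfg$phi_E)
    final_summaries <- sums
    for (M in subgroup_levels()) {
      if (!open[[as.character(M)]]) next
      sel <- select_final(sums, cfg, M)
      if (!is.null(sel)) {
        selection$dose_index[selection$subgroup == M] <- sel$dose_index
        selection$schedule_index[selection$subgroup == M] <- sel$schedule_index
      }
    }
  }
  counts <- data |>
    count(.data$dose_index, .data$schedule_index, .data$subgroup,
          name = "n_treated") |>
    right_join(crossing(dose_index = seq_len(grid$J),
                        schedule_index = seq_len(grid$K),
                        subgroup = subgroup_levels()),
               by = c("dose_index", "schedule_index", "subgroup")) |>
    mutate(n_treated = dplyr::coalesce(.data$n_treated, 0L)) |>
    arrange(.data$subgroup, .data$schedule_index, .data$dose_index)
  structure(list(selection = selection, counts = counts,
                 n_enrolled = nrow(data), early_stop = early_stop,
                 trace = trace, seed = as.integer(seed), data = data,
                 summaries = final_summaries),
            class = "dsd_trial")
}

#' @export
print.dsd_trial <- function(x, ...) {
  cat("<dsd_trial> ", x$n_enrolled, " patients enrolled",
      if (x$early_stop) " (terminated early)", "\n", sep = "")
  print(x$selection)
  invisible(x)
}

#' Write a trial decision trace as JSON lines
#'
#' One JSON object per cohort (stage, interim sample size, admissible sets,
#' randomization probabilities, assignments) for auditability.
#'
#' @param trial A [run_trial()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_trace <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in trial$trace) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6), con)
  }
  invisible(path)
}

#' Operating characteristics over replicated trials
#'
#' Repeats [run_trial()] over independent replicate seeds (derived
#' deterministically from `seed`, so results do not depend on execution
#' order) and aggregates selection percentages and mean patient allocation
#' per dose-schedule-subgroup, the percentage of replicates selecting no
#' combination per subgroup, and the mean sample size.
#'
#' @param s A `dsd_scenario`.
#' @param cfg A [design_config()].
#' @param n_reps Number of replicate trials.
#' @param seed Master seed.
#' @return An object of class `dsd_oc` with `cells` (tibble: `sel_pct`,
#'   `mean_n` per cell), `none` (percent-none per subgroup),
#'   `mean_sample_size`, `pct_early_stop`, `n_reps`.
#' @export
operating_characteristics <- function(s, cfg, n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) abort("`n_reps` must be at least 1")
  seeds <- replicate_seeds(seed, n_reps)
  trials <- purrr::map(seeds, ~ run_trial(s, cfg, seed = .x))
  sel <- purrr::map(trials, "selection") |> list_rbind()
  counts <- purrr::map(trials, "counts") |> list_rbind()
  cells <- counts |>
    group_by(.data$dose_index, .data$schedule_index, .data$subgroup) |>
    summarise(mean_n = sum(.data$n_treated) / n_reps, .groups = "drop")
  sel_pct <- sel |>
    filter(!is.na(.data$dose_index)) |>
    count(.data$dose_index, .data$schedule_index, .data$subgroup) |>
    mutate(sel_pct = 100 * .data$n / n_reps) |>
    select(-"n")
  cells <- cells |>
    left_join(sel_pct, by = c("dose_index", "schedule_index", "subgroup")) |>
    mutate(sel_pct = dplyr::coalesce(.data$sel_pct, 0)) |>
    arrange(.data$subgroup, .data$schedule_index, .data$dose_index)
  none <- sel |>
    group_by(.data$subgroup) |>
    summarise(pct_none = 100 * mean(is.na(.data$dose_index)), .groups = "drop")
  structure(list(cells = cells, none = none,
                 mean_sample_size = mean(purrr::map_dbl(trials, "n_enrolled")),
                 pct_early_stop = 100 * mean(purrr::map_lgl(trials,
                                                            "early_stop")),
                 n_reps = n_reps, seed = as.integer(seed),
                 variant = cfg$variant, scenario = s$name),
            class = "dsd_oc")
}

#' @export
print.dsd_oc <- function(x, ...) {
  cat("<dsd_oc> ", x$n_reps, " replicate trials, scenario ", x$scenario,
      " (", x$variant, " design)\n", sep = "")
  cat("  mean sample size ", round(x$mean_sample_size, 1), ", early stop ",
      round(x$pct_early_stop, 1), "%\n", sep = "")
  print(x$cells |> arrange(desc(.data$sel_pct)), n = 6)
  invisible(x)
}

#' @rdname tidy.dsd_oc
#' @export
tidy.dsd_oc <- function(x, ...) x$cells

#' Tidy and glance methods for operating characteristics
#'
#' `tidy()` returns the per-cell selection percentage and mean allocation;
#' `glance()` the trial-level summary.
#'
#' @param x A `dsd_oc`.
#' @param ... Unused.
#' @name tidy.dsd_oc
#' @export
glance.dsd_oc <- function(x, ...) {
  tibble(n_reps = x$n_reps, mean_sample_size = x$mean_sample_size,
         pct_early_stop = x$pct_early_stop,
         pct_none_neg = x$none$pct_none[x$none$subgroup == 0],
         pct_none_pos = x$none$pct_none[x$none$subgroup == 1])
}

#' Selection-percentage and allocation plot
#'
#' @param object A `dsd_oc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsd_oc <- function(object, ...) {
  df <- object$cells |>
    mutate(combo = paste0("d", .data$dose_index, ",s", .data$schedule_index),
           subgroup = factor(.data$subgroup,
                             labels = c("marker-negative", "marker-positive")))
  ggplot(df, aes(.data$combo, .data$sel_pct, fill = .data$mean_n)) +
    geom_col() +
    facet_wrap(~subgroup) +
    labs(x = "dose-schedule combination", y = "selection %",
         fill = "mean patients") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Export operating characteristics as CSV
#'
#' Rows are (dose, schedule, subgroup) cells with selection percentage and
#' mean allocation.
#'
#' @param oc A `dsd_oc`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_oc_csv <- function(oc, path) {
  write.csv(as.data.frame(oc$cells), path, row.names = FALSE)
  invisible(path)
}
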