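#' Construct a truth scenario
#'
#' A truth scenario fixes, for every (dose, schedule, subgroup) cell, the
#' true mean immune response, the DLT probability, and the ordinal efficacy
#' distribution `(q0, q1, q2)`, together with the Gumbel-copula dependence
#' parameter and the immune-response generation SD. It is the ground truth a
#' simulated trial samples patients from.
#'
#' @param cells Tibble with columns `dose_index`, `schedule_index`,
#'   `subgroup`, `mu_z`, `p_tox`, `q0`, `q1`, `q2` covering the full
#'   `J x K x 2` grid.
#' @param doses Raw dose grid (length `J`).
#' @param schedules Number of schedules or labels.
#' @param copula_theta Gumbel dependence parameter (>= 1).
#' @param sigma_z True immune-response SD used for generation.
#' @param name Optional label.
#' @return An object of class `dsd_scenario`; its `cells` tibble gains
#'   `pi = q1 + q2` and `u_true` is attached by the caller when known.
#' @export
scenario_truth <- function(cells, doses, schedules = 3L, copula_theta = 1.5,
                           sigma_z = 2, name = "custom") {
  grid <- dose_grid(doses, schedules)
  check_scalar_number(copula_theta, "copula_theta", 1)
  check_scalar_number(sigma_z, "sigma_z", 0, strict_lower = TRUE)
  need <- c("dose_index", "schedule_index", "subgroup", "mu_z", "p_tox",
            "q0", "q1", "q2")
  if (!all(need %in% names(cells))) {
    abort(paste("scenario cells need columns:", paste(need, collapse = ", ")))
  }
  cells <- as_tibble(cells) |>
    mutate(across(c("dose_index", "schedule_index", "subgroup"), as.integer)) |>
    arrange(.data$subgroup, .data$schedule_index, .data$dose_index)
  full <- crossing(subgroup = subgroup_levels(),
                   schedule_index = seq_len(grid$K),
                   dose_index = seq_len(grid$J))
  if (nrow(cells) != nrow(full) ||
      !identical(cells |> select("subgroup", "schedule_index", "dose_index") |>
                   as.data.frame(), as.data.frame(full))) {
    abort("scenario cells must cover each (dose, schedule, subgroup) exactly once")
  }
  bad <- abs(cells$q0 + cells$q1 + cells$q2 - 1) > 1e-9
  if (any(bad)) abort("efficacy probabilities must sum to 1 in every cell")
  for (col in c("p_tox", "q0", "q1", "q2")) check_prob(cells[[col]], col, 1e-9)
  cells <- cells |>
    mutate(pi = .data$q1 + .data$q2) |>
    select("dose_index", "schedule_index", "subgroup", "mu_z", "p_tox",
           "q0", "q1", "q2", "pi", dplyr::everything())
  structure(list(cells = cells, grid = grid, copula_theta = copula_theta,
                 sigma_z = sigma_z, name = name),
            class = "dsd_scenario")
}

#' Back-solve the CR/PR probability from a published utility
#'
#' The truth tables publish, per cell, `(mu_z, p, pi, u_true)` but not the
#' split of `pi = Pr(Y > 0)` into SD and CR/PR. Because the utility is
#' linear in `q2` given `(pi, p)`, the CR/PR probability is recovered as
#' `q2 = (u - w1 * pi + w2 * p + penalty(p)) / (1 - w1)` and `q1 = pi - q2`.
#' Utilities printed with one or two decimals carry that rounding into the
#' reconstruction, so `round_tol` permits clipping small out-of-range
#' solutions back into `[0, pi]` (default `1e-6`: strict).
#'
#' @param u_true Published utility.
#' @param pi Probability of SD or better.
#' @param p Toxicity probability.
#' @param weights A [utility_weights()] object.
#' @param round_tol Largest tolerated out-of-range excursion before
#'   clipping; beyond it a consistency error naming the offending values is
#'   raised.
#' @return The CR/PR probability `q2` in `[0, pi]`.
#' @examples
#' derive_q2_from_utility(0.42, pi = 0.7, p = 0.18, utility_weights())
#' @export
derive_q2_from_utility <- function(u_true, pi, p, weights = utility_weights(),
                                   round_tol = 1e-6) {
  pi <- check_prob(pi, "pi"); p <- check_prob(p, "p")
  pen <- switch(weights$penalty,
                fixed = weights$w3 * (p > weights$phi_T),
                proportional = weights$w3 * p * (p > weights$phi_T))
  q2 <- (u_true - weights$w1 * pi + weights$w2 * p + pen) / (1 - weights$w1)
  viol <- pmax(-q2, q2 - pi, 0)
  if (any(viol > round_tol)) {
    i <- which.max(viol)
    abort(sprintf(
      paste0("utility %.4g with pi = %.4g, p = %.4g back-solves to q2 = %.4g, ",
             "outside [0, pi] under the %s-penalty convention"),
      u_true[i], pi[i], p[i], q2[i], weights$penalty))
  }
  pmin(pmax(q2, 0), pi)
}

#' Load a built-in truth scenario
#'
#' Eight scenarios covering a common optimum across subgroups, subgroup-
#' specific optimal schedules, subgroup-specific optimal doses, and multiple
#' optima, on a 3-dose (0.1, 0.5, 0.9) by 3-schedule grid. The published
#' `(mu_z, p, pi, u_true)` quadruples are completed into full efficacy
#' distributions via [derive_q2_from_utility()]; because published utilities
#' are rounded to at most two decimals, the back-solve is allowed to clip
#' reconstruction error up to `round_tol` (default 0.06; rounding a 1-dp
#' utility perturbs `q2` by up to `0.05 / (1 - w1) = 0.1`).
#'
#' @param id Scenario number, 1 to 8.
#' @param weights A [utility_weights()] object (fixed-penalty default; the
#'   published utilities are only consistent with this convention).
#' @param copula_theta Gumbel dependence parameter used for generation.
#' @param sigma_z True immune-response SD (not published; default 2).
#' @param round_tol Clipping tolerance passed to [derive_q2_from_utility()].
#' @return A `dsd_scenario` whose `cells` tibble also carries the published
#'   `u_true`.
#' @export
load_builtin_scenario <- function(id, weights = utility_weights(),
                                  copula_theta = 1.5, sigma_z = 2,
                                  round_tol = 0.06) {
  if (!(length(id) == 1L && id %in% 1:8)) {
    abort("`id` must be a single integer between 1 and 8")
  }
  raw <- .builtin_scenarios[[id]]
  cells <- purrr::map(subgroup_levels(), function(M) {
    m <- if (M == 0L) raw$m0 else raw$m1
    crossing(dose_index = 1:3, schedule_index = 1:3) |>
      arrange(.data$schedule_index, .data$dose_index) |>
      mutate(subgroup = M,
             mu_z  = map_dbl(row_number(), ~ m[cells_row(.x), cells_col(.x, 1)]),
             p_tox = map_dbl(row_number(), ~ m[cells_row(.x), cells_col(.x, 2)]),
             pi    = map_dbl(row_number(), ~ m[cells_row(.x), cells_col(.x, 3)]),
             u_true = map_dbl(row_number(), ~ m[cells_row(.x), cells_col(.x, 4)]))
  }) |> list_rbind()
  cells <- cells |>
    mutate(q2 = derive_q2_from_utility(.data$u_true, .data$pi, .data$p_tox,
                                       weights, round_tol = round_tol),
           q1 = .data$pi - .data$q2,
           q0 = 1 - .data$pi)
  s <- scenario_truth(cells |> select(-"pi"), doses = c(0.1, 0.5, 0.9),
                      schedules = 3L, copula_theta = copula_theta,
                      sigma_z = sigma_z, name = paste0("builtin-", id))
  s$id <- as.integer(id)
  s
}

# Row/column helpers for the packed 3 x 12 scenario matrices: rows iterate
# doses, column blocks iterate schedules (4 numbers per schedule).
cells_row <- function(i) ((i - 1L) %% 3L) + 1L
cells_col <- function(i, field) (((i - 1L) %/% 3L)) * 4L + field

#' Validate the internal consistency of a truth scenario
#'
#' Checks, per cell: probability validity, `q2` within `[0, pi]`, biomarker
#' subgroup dominance (marker-positive `q2` and `pi` at least the
#' marker-negative values), and monotone nondecreasing mean immune response
#' in dose within each (schedule, subgroup). For scenarios reconstructed
#' from published tables the dominance checks use tolerances reflecting the
#' printed precision: `pi` values are printed to two decimals
#' (`tol_pi_dom`), and back-solved `q2` values inherit up to
#' `0.05 / (1 - w1)` of rounding error each from one-decimal utilities
#' (`tol_q2_dom`).
#'
#' @param s A `dsd_scenario`.
#' @param weights A [utility_weights()] object (used to re-evaluate
#'   utilities when the scenario carries published `u_true` values).
#' @param tol_pi_dom,tol_q2_dom Dominance tolerances.
#' @return A list of class `dsd_validation` with `pass` (logical) and
#'   `report`, a tibble of per-cell checks (`check`, `dose_index`,
#'   `schedule_index`, `subgroup`, `ok`, `detail`).
#' @export
validate_scenario <- function(s, weights = utility_weights(),
                              tol_pi_dom = 0.0101, tol_q2_dom = 0.2) {
  cells <- s$cells
  rep1 <- cells |>
    mutate(check = "probability_simplex",
           ok = abs(.data$q0 + .data$q1 + .data$q2 - 1) <= 1e-9 &
             is_prob(.data$p_tox) & is_prob(.data$q0) &
             is_prob(.data$q1, 1e-9) & is_prob(.data$q2),
           detail = "q0+q1+q2 = 1 and all probabilities in [0,1]")
  rep2 <- cells |>
    mutate(check = "q2_within_pi",
           ok = .data$q2 >= -1e-9 & .data$q2 <= .data$pi + 1e-9,
           detail = "q2 in [0, pi]")
  dom <- cells |>
    select("dose_index", "schedule_index", "subgroup", "q2", "pi") |>
    pivot_wider(names_from = "subgroup", values_from = c("q2", "pi")) |>
    mutate(check = "subgroup_dominance",
           subgroup = 1L,
           ok = .data$q2_1 >= .data$q2_0 - tol_q2_dom &
             .data$pi_1 >= .data$pi_0 - tol_pi_dom,
           detail = "marker-positive q2 and pi dominate (within printed rounding)") |>
    select("check", "dose_index", "schedule_index", "subgroup", "ok", "detail")
  mono <- cells |>
    group_by(.data$schedule_index, .data$subgroup) |>
    arrange(.data$dose_index, .by_group = TRUE) |>
    mutate(check = "mu_z_monotone",
           ok = .data$mu_z >= cummax(dplyr::lag(.data$mu_z, default = -Inf)) - 1e-9,
           detail = "mu_z nondecreasing in dose") |>
    ungroup() |>
    select("check", "dose_index", "schedule_index", "subgroup", "ok", "detail")
  utl <- NULL
  if ("u_true" %in% names(cells)) {
    # Re-evaluated utility must agree with the published value at its
    # printed precision (half a unit in the last printed decimal).
    clamp <- function(x) pmin(pmax(x, 0), 1)
    q2c <- clamp(cells$q2)
    q1c <- pmin(clamp(cells$q1), 1 - q2c)   # keep evaluable when flagged invalid
    utl <- cells |>
      mutate(u_eval = utility(q1c, q2c, clamp(.data$p_tox), weights),
             tol = if_else(.data$u_true == round(.data$u_true, 1), 0.05, 0.005),
             check = "utility_reproduced",
             ok = abs(.data$u_eval - .data$u_true) <= .data$tol + 1e-12,
             detail = "utility re-evaluates to the printed value") |>
      select("check", "dose_index", "schedule_index", "subgroup", "ok", "detail")
  }
  report <- bind_rows(
    rep1 |> select("check", "dose_index", "schedule_index", "subgroup", "ok",
                   "detail"),
    rep2 |> select("check", "dose_index", "schedule_index", "subgroup", "ok",
                   "detail"),
    dom, mono, utl)
  structure(list(pass = all(report$ok), report = report),
            class = "dsd_validation")
}

#' @export
print.dsd_validation <- function(x, ...) {
  cat("<dsd_validation> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (!x$pass) {
    print(x$report |> filter(!.data$ok), n = 20)
  }
  invisible(x)
}

#' True subgroup-specific optimal dose-schedule combinations
#'
#' For each subgroup, the admissible combinations (`p < phi_T` and
#' `pi > phi_E`) with the highest true utility; ties within `tie_tol` are
#' all returned (use `tie_tol = 0.0101` to treat utilities that agree to
#' their printed two-decimal precision as tied, as the published tables
#' do). An empty tibble for a subgroup means no combination is acceptable.
#'
#' @param s A `dsd_scenario`.
#' @param weights A [utility_weights()] object.
#' @param phi_T,phi_E Toxicity upper / efficacy lower limits.
#' @param tie_tol Utilities within `tie_tol` of the maximum count as tied.
#' @return Tibble with columns `subgroup`, `dose_index`, `schedule_index`,
#'   `u_true`.
#' @export
true_optimal <- function(s, weights = utility_weights(), phi_T = 0.3,
                         phi_E = 0.3, tie_tol = 1e-9) {
  adm <- s$cells |>
    mutate(u = utility(.data$q1, .data$q2, .data$p_tox, weights)) |>
    filter(.data$p_tox < phi_T, .data$pi > phi_E)
  if (nrow(adm) == 0L) {
    return(tibble(subgroup = integer(), dose_index = integer(),
                  schedule_index = integer(), u_true = numeric()))
  }
  adm |>
    group_by(.data$subgroup) |>
    filter(.data$u >= max(.data$u) - tie_tol) |>
    ungroup() |>
    arrange(.data$subgroup, .data$dose_index, .data$schedule_index) |>
    select("subgroup", "dose_index", "schedule_index", u_true = "u")
}

#' Read a truth scenario from CSV
#'
#' One row per (dose, schedule, subgroup) with columns `dose_index`,
#' `schedule_index`, `subgroup`, `mu_z`, `p_tox`, `q0`, `q1`, `q2`
#' (probabilities as decimals, header required). Supports arbitrary
#' `J x K` grids.
#'
#' @param path CSV file path.
#' @param doses Raw dose grid matching the dose indices in the file.
#' @param schedules Number of schedules or labels.
#' @inheritParams scenario_truth
#' @return A `dsd_scenario`.
#' @export
read_scenario_csv <- function(path, doses, schedules = NULL,
                              copula_theta = 1.5, sigma_z = 2) {
  cells <- as_tibble(read.csv(path))
  if (is.null(schedules)) schedules <- max(cells$schedule_index)
  scenario_truth(cells, doses, schedules, copula_theta, sigma_z,
                 name = basename(path))
}

#' @export
print.dsd_scenario <- function(x, ...) {
  cat("<dsd_scenario> ", x$name, ": ", x$grid$J, " doses x ", x$grid$K,
      " schedules, copula theta = ", x$copula_theta,
      ", sigma_z = ", x$sigma_z, "\n", sep = "")
  print(x$cells, n = 6)
  invisible(x)
}

#' Dose-response curves of a truth scenario
#'
#' Plots the true mean immune response, toxicity probability, and
#' `Pr(Y > 0)` against dose, by schedule and biomarker subgroup.
#'
#' @param s A `dsd_scenario`.
#' @return A ggplot object.
#' @export
plot_scenario <- function(s) {
  df <- s$cells |>
    mutate(dose = s$grid$raw[.data$dose_index],
           schedule = factor(s$grid$schedules[.data$schedule_index]),
           subgroup = factor(.data$subgroup,
                             labels = c("marker-negative", "marker-positive"))) |>
    select("dose", "schedule", "subgroup", `mean immune response` = "mu_z",
           `Pr(DLT)` = "p_tox", `Pr(Y > 0)` = "pi") |>
    pivot_longer(-c("dose", "schedule", "subgroup"),
                 names_to = "endpoint", values_to = "value")
  ggplot(df, aes(.data$dose, .data$value, colour = .data$schedule)) +
    geom_line() + geom_point(size = 1) +
    facet_grid(endpoint ~ subgroup, scales = "free_y") +
    labs(x = "dose", y = NULL, colour = "schedule",
         title = paste("Truth scenario", s$name)) +
    theme_bw()
}
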