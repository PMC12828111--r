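#' Utility weights for the risk-benefit tradeoff
#'
#' The utility of a dose-schedule combination converts the ordinal efficacy
#' distribution into a CR/PR-equivalent rate and charges toxicity:
#' `U = q2 + w1 * q1 - w2 * p - penalty(p)`. `w1` converts SD to CR/PR
#' (0.5 = two SDs are worth one CR/PR), `w2` is the CR/PR price of a unit of
#' toxicity, and `w3` is an extra penalty applied when `p` exceeds the
#' toxicity limit `phi_T`. The default penalty convention is `fixed`
#' (`w3 * I(p > phi_T)`), which is the convention the built-in truth tables
#' are consistent with; `proportional` (`w3 * p * I(p > phi_T)`) is
#' available as an alternative.
#'
#' @param w1 Weight in (0, 1) converting SD to CR/PR.
#' @param w2 Positive toxicity weight.
#' @param w3 Positive over-threshold penalty weight.
#' @param phi_T Toxicity upper limit.
#' @param penalty `"fixed"` or `"proportional"`.
#' @return A list of class `dsd_utility_weights`.
#' @export
utility_weights <- function(w1 = 0.5, w2 = 0.3, w3 = 1.2, phi_T = 0.3,
                            penalty = c("fixed", "proportional")) {
  check_scalar_number(w1, "w1", 0, 1, strict_lower = TRUE)
  if (w1 >= 1) abort("`w1` must be in (0, 1)")
  check_scalar_number(w2, "w2", 0, strict_lower = TRUE)
  check_scalar_number(w3, "w3", 0, strict_lower = TRUE)
  check_prob(phi_T, "phi_T")
  structure(list(w1 = w1, w2 = w2, w3 = w3, phi_T = phi_T,
                 penalty = match.arg(penalty)),
            class = "dsd_utility_weights")
}

#' Risk-benefit utility of a dose-schedule combination
#'
#' @param q1,q2 Probabilities of SD and CR/PR (`q1 + q2 <= 1`).
#' @param p Toxicity probability.
#' @param weights A [utility_weights()] object.
#' @return Numeric utility (vectorized over the inputs).
#' @examples
#' utility(q1 = 0.452, q2 = 0.248, p = 0.18, utility_weights())
#' @export
utility <- function(q1, q2, p, weights = utility_weights()) {
  q1 <- check_prob(q1, "q1"); q2 <- check_prob(q2, "q2")
  p <- check_prob(p, "p")
  if (any(q1 + q2 > 1 + 1e-9)) abort("`q1 + q2` must not exceed 1")
  pen <- switch(weights$penalty,
                fixed = weights$w3 * (p > weights$phi_T),
                proportional = weights$w3 * p * (p > weights$phi_T))
  q2 + weights$w1 * q1 - weights$w2 * p - pen
}

#' Plug-in posterior-mean utilities
#'
#' Applies [utility()] to the posterior means `(q1_hat, q2_hat, p_hat)` of
#' every (dose, schedule, subgroup) cell; the over-threshold penalty
#' indicator is evaluated at the posterior-mean toxicity `p_hat`.
#'
#' @param summaries A [posterior_summaries()] tibble.
#' @param weights A [utility_weights()] object.
#' @return The summaries tibble with an added `utility` column.
#' @export
estimated_utilities <- function(summaries, weights = utility_weights()) {
  summaries |>
    mutate(utility = utility(.data$q1_hat, .data$q2_hat, .data$p_hat, weights))
}

#' Trial design configuration
#'
#' All design constants of the two-stage dose-schedule finding algorithm:
#' the grid, total sample size and cohort size, marker-positive prevalence,
#' clinical limits (`phi_T`, `phi_E`), the stage-I Beta-Binomial screening
#' cutoff `c_i`, the stage-II posterior admissibility cutoffs `c_t` and
#' `c_e`, the utility weights, model hyperparameters, prior, MCMC settings,
#' design variant, and the floor applied to nonpositive utilities in
#' adaptive randomization.
#'
#' @param doses Raw dose grid.
#' @param schedules Number of schedules or labels.
#' @param n_max Maximum number of enrolled patients.
#' @param cohort_size Patients per cohort.
#' @param prevalence Marker-positive prevalence.
#' @param phi_T,phi_E Toxicity upper / efficacy lower limits.
#' @param c_i Stage-I safety screen cutoff (schedule closes when
#'   `Pr(p < phi_T) <= c_i`).
#' @param c_t,c_e Stage-II admissibility cutoffs (strict `>` comparisons).
#' @param weights A [utility_weights()] object.
#' @param hyper A [model_hyper()] object (recycled to `K` schedules).
#' @param prior A [prior_spec()] object.
#' @param mcmc An [mcmc_config()] object.
#' @param variant Design variant: `"proposed"`, `"dose_adjusted"`,
#'   `"alternative1"` (ignores the immune response), or `"alternative2"`
#'   (parametric proportional-odds efficacy).
#' @param rand_floor Utility floor used in randomization probabilities.
#' @param kappa Beta prior pseudo-counts `(kappa1, kappa2)` of the stage-I
#'   Beta-Binomial model.
#' @return A list of class `dsd_design_config`.
#' @export
design_config <- function(doses = c(0.1, 0.5, 0.9), schedules = 3L,
                          n_max = 120L, cohort_size = 3L, prevalence = 0.5,
                          phi_T = 0.3, phi_E = 0.3,
                          c_i = 0.05, c_t = 0.2, c_e = 0.2,
                          weights = utility_weights(phi_T = phi_T),
                          hyper = NULL, prior = prior_spec(),
                          mcmc = mcmc_config(),
                          variant = c("proposed", "dose_adjusted",
                                      "alternative1", "alternative2"),
                          rand_floor = 0.01, kappa = c(0.1, 0.2)) {
  grid <- dose_grid(doses, schedules)
  if (is.null(hyper)) hyper <- model_hyper(K = grid$K)
  hyper$zeta0 <- rep_len(hyper$zeta0, grid$K)
  for (nm in c("c_i", "c_t", "c_e", "prevalence", "phi_T", "phi_E")) {
    check_prob(get(nm), nm)
  }
  if (c_i <= 0 || c_i >= 1 || c_t <= 0 || c_t >= 1 || c_e <= 0 || c_e >= 1) {
    abort("cutoffs c_i, c_t, c_e must lie strictly inside (0, 1)")
  }
  cohort_size <- as.integer(cohort_size); n_max <- as.integer(n_max)
  if (cohort_size < 1L || n_max < cohort_size) {
    abort("need cohort_size >= 1 and n_max >= cohort_size")
  }
  check_scalar_number(rand_floor, "rand_floor", 0, strict_lower = TRUE)
  structure(list(grid = grid, n_max = n_max, cohort_size = cohort_size,
                 prevalence = prevalence, phi_T = phi_T, phi_E = phi_E,
                 c_i = c_i, c_t = c_t, c_e = c_e, weights = weights,
                 hyper = hyper, prior = prior, mcmc = mcmc,
                 variant = match.arg(variant), rand_floor = rand_floor,
                 kappa = kappa),
            class = "dsd_design_config")
}

#' Start a stage-I escalation state
#'
#' Stage I escalates independently within each schedule, one cohort at a
#' time in round-robin order, starting every schedule at its lowest dose.
#' The state records per-combination toxicity counts, the highest tried
#' dose per schedule, and which schedules remain open.
#'
#' @param cfg A [design_config()].
#' @return A list of class `dsd_stage1_state` with fields `counts`
#'   (tibble of `n`, `m` per combination), `h`, `open`, `seeded`, `cursor`.
#' @export
stage1_init <- function(cfg) {
  grid <- cfg$grid
  structure(list(
    counts = crossing(dose_index = seq_len(grid$J),
                      schedule_index = seq_len(grid$K)) |>
      mutate(n = 0L, m = 0L),
    h = rep(0L, grid$K), open = rep(TRUE, grid$K),
    cursor = 0L), class = "dsd_stage1_state")
}

#' Record stage-I cohort outcomes
#'
#' @param state A `dsd_stage1_state`.
#' @param j,k Combination the cohort was treated at.
#' @param n_treated,n_tox Cohort size and number of DLTs observed.
#' @return The updated state.
#' @export
stage1_record <- function(state, j, k, n_treated, n_tox) {
  stopifnot(n_tox >= 0L, n_tox <= n_treated)
  i <- which(state$counts$dose_index == j & state$counts$schedule_index == k)
  state$counts$n[i] <- state$counts$n[i] + as.integer(n_treated)
  state$counts$m[i] <- state$counts$m[i] + as.integer(n_tox)
  state$h[k] <- max(state$h[k], as.integer(j))
  state
}

#' One stage-I escalation decision
#'
#' Visits open schedules in round-robin order. On a schedule's first visit
#' the cohort is assigned to its lowest dose. Afterwards, the highest tried
#' dose `(h_k, k)` is screened with the Beta-Binomial posterior
#' ([beta_binomial_safety_prob()]): if `Pr(p < phi_T) <= c_i` or the top
#' dose has been tried, the schedule closes; otherwise the next cohort is
#' assigned one dose higher. Stage I completes when all schedules close.
#'
#' @param state A `dsd_stage1_state` (with outcomes recorded via
#'   [stage1_record()]).
#' @param cfg A [design_config()].
#' @return A list: either `list(complete = FALSE, dose_index, schedule_index,
#'   state)` giving the next cohort's assignment, or `list(complete = TRUE,
#'   state)`.
#' @export
stage1_step <- function(state, cfg) {
  if (!any(state$open)) abort("stage I is already complete")
  K <- cfg$grid$K
  for (step in seq_len(K)) {
    k <- (state$cursor %% K) + 1L
    state$cursor <- state$cursor + 1L
    if (!state$open[k]) next
    if (state$h[k] == 0L) {                       # first visit: start at d1
      return(list(complete = FALSE, dose_index = 1L, schedule_index = k,
                  state = state))
    }
    i <- which(state$counts$dose_index == state$h[k] &
                 state$counts$schedule_index == k)
    safe <- beta_binomial_safety_prob(state$counts$m[i], state$counts$n[i],
                                      cfg$phi_T, cfg$kappa[1], cfg$kappa[2])
    if (safe <= cfg$c_i || state$h[k] >= cfg$grid$J) {
      state$open[k] <- FALSE
      next
    }
    return(list(complete = FALSE, dose_index = state$h[k] + 1L,
                schedule_index = k, state = state))
  }
  list(complete = TRUE, state = state)
}

#' Admissible dose-schedule combinations
#'
#' A combination is admissible for subgroup `M` when its posterior
#' probability of acceptable toxicity exceeds `c_t` and its posterior
#' probability of acceptable efficacy exceeds `c_e` (both strict).
#'
#' @param summaries A [posterior_summaries()] tibble.
#' @param cfg A [design_config()].
#' @return The summaries tibble filtered to admissible rows (columns
#'   `subgroup`, `dose_index`, `schedule_index` and the posterior columns).
#' @export
admissible_set <- function(summaries, cfg) {
  summaries |>
    filter(.data$prob_safe > cfg$c_t, .data$prob_eff > cfg$c_e)
}

#' Adaptive randomization probabilities
#'
#' Assignment probabilities proportional to the posterior-mean utility over
#' the admissible set, with nonpositive utilities floored at `floor` so the
#' vector stays a proper distribution while nearly excluding undesirable
#' combinations.
#'
#' @param utils Tibble with columns `dose_index`, `schedule_index`,
#'   `utility` for one subgroup's admissible set.
#' @param floor Positive utility floor.
#' @return The input tibble with an added `psi` column summing to 1.
#' @export
randomization_probabilities <- function(utils, floor = 0.01) {
  if (nrow(utils) == 0L) abort("admissible set is empty; no randomization possible")
  w <- pmax(utils$utility, floor)
  utils |> mutate(psi = w / sum(w))
}

#' Final dose-schedule selection for one subgroup
#'
#' Selects the admissible combination with the largest posterior-mean
#' utility; ties (within numerical precision) resolve to the lowest dose
#' index, then the lowest schedule index. Returns `NULL` when the
#' admissible set is empty (no acceptable dose for that subgroup).
#'
#' @param summaries A [posterior_summaries()] tibble.
#' @param cfg A [design_config()].
#' @param subgroup Subgroup indicator (0 or 1).
#' @return A one-row tibble (`subgroup`, `dose_index`, `schedule_index`,
#'   `utility`) or `NULL`.
#' @export
select_final <- function(summaries, cfg, subgroup) {
  adm <- admissible_set(summaries, cfg) |>
    filter(.data$subgroup == !!subgroup) |>
    estimated_utilities(cfg$weights)
  if (nrow(adm) == 0L) return(NULL)
  adm |>
    filter(.data$utility >= max(.data$utility) - 1e-12) |>
    arrange(.data$dose_index, .data$schedule_index) |>
    slice(1) |>
    select("subgroup", "dose_index", "schedule_index", "utility")
}
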