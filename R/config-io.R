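#' Read a design configuration from YAML
#'
#' The YAML file mirrors [design_config()] field-for-field; nested blocks
#' `weights`, `hyper`, `prior`, `mcmc` are passed to the corresponding
#' constructors. Missing fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A [design_config()] object.
#' @export
read_design_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, ctor, extra = list()) {
    do.call(ctor, c(y[[block]] %||% list(), extra))
  }
  args <- y[setdiff(names(y), c("weights", "hyper", "prior", "mcmc"))]
  args$weights <- take("weights", utility_weights)
  K <- if (length(y$schedules) > 1L) length(y$schedules) else
    (y$schedules %||% 3L)
  args$hyper <- take("hyper", model_hyper, list(K = K))
  args$prior <- take("prior", prior_spec)
  args$mcmc <- take("mcmc", mcmc_config)
  do.call(design_config, args)
}

#' @rdname tidy.dsd_trial
#' @export
tidy.dsd_trial <- function(x, ...) {
  x$counts |>
    left_join(x$selection |> mutate(selected = TRUE),
              by = c("dose_index", "schedule_index", "subgroup")) |>
    mutate(selected = dplyr::coalesce(.data$selected, FALSE))
}

#' Tidy and glance methods for a simulated trial
#'
#' `tidy()` returns per-cell patient counts with a `selected` flag;
#' `glance()` the trial-level summary.
#'
#' @param x A `dsd_trial`.
#' @param ... Unused.
#' @name tidy.dsd_trial
#' @export
glance.dsd_trial <- function(x, ...) {
  tibble(n_enrolled = x$n_enrolled, early_stop = x$early_stop,
         selected_neg = selection_label(x$selection, 0L),
         selected_pos = selection_label(x$selection, 1L),
         seed = x$seed)
}

selection_label <- function(selection, M) {
  row <- selection |> filter(.data$subgroup == M)
  if (is.na(row$dose_index)) "none"
  else paste0("d", row$dose_index, ",s", row$schedule_index)
}
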