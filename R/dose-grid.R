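#' Standardize a dose grid to dispersion 0.5
#'
#' Rescales raw drug amounts so that their population standard deviation is
#' 0.5, the covariate scale on which the weakly-informative priors for the
#' dose-slope parameters (`nu` in the plateau immune-response model, `beta1`
#' in the logistic toxicity model) are stated. The same scaled doses are used
#' in the likelihood, so prior and likelihood share one dose scale.
#'
#' @param raw_doses Numeric vector of at least two strictly increasing,
#'   positive doses (drug-amount units).
#' @return Numeric vector of scaled doses with population SD exactly 0.5.
#' @examples
#' standardize_doses(c(0.1, 0.5, 0.9))
#' @export
standardize_doses <- function(raw_doses) {
  if (!is.numeric(raw_doses) || length(raw_doses) < 2L) {
    abort("`raw_doses` must contain at least two doses")
  }
  if (any(diff(raw_doses) <= 0)) {
    abort("`raw_doses` must be strictly increasing")
  }
  s <- pop_sd(raw_doses)
  if (s == 0) abort("doses are constant; cannot standardize")
  raw_doses * 0.5 / s
}

#' Dose-schedule grid
#'
#' Bundles the raw dose grid, its standardized version (dispersion 0.5, see
#' [standardize_doses()]), and the schedule labels. All model and design
#' functions take their dose-schedule geometry from this object.
#'
#' @param doses Strictly increasing positive raw doses (length `J`).
#' @param schedules Either an integer number of schedules `K` or a character
#'   vector of `K` schedule labels.
#' @return An object of class `dsd_grid` with fields `raw`, `scaled`,
#'   `schedules`, `J`, `K`.
#' @examples
#' dose_grid(c(0.1, 0.5, 0.9), 3)
#' @export
dose_grid <- function(doses, schedules = 3L) {
  scaled <- standardize_doses(doses)
  if (is.numeric(schedules) && length(schedules) == 1L) {
    schedules <- paste0("s", seq_len(schedules))
  }
  structure(
    list(raw = as.numeric(doses), scaled = scaled,
         schedules = as.character(schedules),
         J = length(doses), K = length(schedules)),
    class = "dsd_grid")
}

#' @export
print.dsd_grid <- function(x, ...) {
  cat("<dsd_grid> ", x$J, " doses x ", x$K, " schedules\n", sep = "")
  cat("  raw:    ", paste(format(x$raw), collapse = ", "), "\n", sep = "")
  cat("  scaled: ", paste(format(round(x$scaled, 5)), collapse = ", "),
      "  (population SD 0.5)\n", sep = "")
  invisible(x)
}
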