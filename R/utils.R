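# Internal helpers shared across modules.

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

is_prob <- function(x, tol = 0) {
  is.numeric(x) & !is.na(x) & x >= -tol & x <= 1 + tol
}

check_prob <- function(x, name, tol = 1e-12) {
  if (!all(is_prob(x, tol))) {
    abort(sprintf("`%s` must be a probability in [0, 1], got %s",
                  name, paste(signif(x[!is_prob(x, tol)], 4), collapse = ", ")))
  }
  pmin(pmax(x, 0), 1)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range", name, format(x)))
  }
  as.numeric(x)
}

# Population (divide-by-n) standard deviation; the dose-standardization
# convention, so that a two-point grid {1, 2} has dispersion 0.5.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

subgroup_levels <- function() c(0L, 1L)

# Deterministic per-replicate seed stream: pre-drawn under the master seed so
# replicate r always receives the same seed regardless of execution order.
replicate_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
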