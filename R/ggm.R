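#' Gamma-Gompertz-Makeham parameter set
#'
#' Bundles the four parameters of the gamma-Gompertz-Makeham (GGM) mortality
#' model together with the starting age to which they are anchored. The hazard
#' for an individual with frailty `z` at model age `x` (years since
#' `start_age`) is `z * a * exp(b * x) + c`; frailty is gamma-distributed with
#' mean 1 and variance `gamma`.
#'
#' @param a Baseline hazard level at the starting age (per year, > 0).
#' @param b Rate of exponential (Gompertz) increase of the hazard with age
#'   (per year, > 0).
#' @param c Age-independent (Makeham) hazard component (per year, >= 0).
#' @param gamma Variance of the mean-1 gamma frailty distribution
#'   (dimensionless, >= 0); `gamma = 0` is the homogeneous model.
#' @param start_age Calendar age at which model age `x = 0` (integer years,
#'   >= 0).
#'
#' @return An object of class `ggm_params`.
#' @examples
#' ggm_params(a = 0.02, b = 0.1, c = 0.005, gamma = 0.2, start_age = 40)
#' @export
ggm_params <- function(a, b, c = 0, gamma = 0, start_age = 0) {
  stopifnot(
    is.numeric(a), length(a) == 1L, is.finite(a),
    is.numeric(b), length(b) == 1L, is.finite(b),
    is.numeric(c), length(c) == 1L, is.finite(c),
    is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
    is.numeric(start_age), length(start_age) == 1L
  )
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (b <= 0) stop("`b` must be > 0", call. = FALSE)
  if (c < 0) stop("`c` must be >= 0", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (start_age < 0) stop("`start_age` must be >= 0", call. = FALSE)
  structure(
    list(a = a, b = b, c = c, gamma = gamma, start_age = as.integer(start_age)),
    class = "ggm_params"
  )
}

#' @export
print.ggm_params <- function(x, ...) {
  cat("<ggm_params>\n")
  cat(sprintf("  a = %.6g  b = %.6g  c = %.6g  gamma = %.6g\n",
              x$a, x$b, x$c, x$gamma))
  cat(sprintf("  start_age = %d (model age x = 0)\n", x$start_age))
  invisible(x)
}

#' Conditional Gompertz-Makeham hazard for a given frailty
#'
#' Hazard rate `z * a * exp(b * x) + c` for an individual with frailty
#' multiplier `z` at model age `x`. Frailty acts as a proportional hazard on
#' the age-dependent (Gompertz) part only; the Makeham term `c` is shared by
#' all individuals.
#'
#' @param x Model age(s) in years since `params$start_age` (>= 0).
#' @param z Frailty multiplier(s) (> 0). Recycled against `x`.
#' @param params A [ggm_params()] object.
#'
#' @return Hazard rate(s), per year.
#' @examples
#' p <- ggm_params(a = 0.02, b = 0.1, c = 0.005)
#' ggm_hazard(0:5, z = 1, params = p)
#' @export
ggm_hazard <- function(x, z = 1, params) {
  stopifnot(inherits(params, "ggm_params"), is.numeric(x), is.numeric(z))
  if (any(x < 0)) stop("model age `x` must be >= 0", call. = FALSE)
  if (any(z <= 0)) stop("frailty `z` must be > 0", call. = FALSE)
  z * params$a * exp(params$b * x) + params$c
}

#' Marginal (population-level) GGM hazard
#'
#' The unconditional hazard after integrating gamma-distributed frailty out
#' of the cohort, accounting for within-cohort selection of the robust:
#' `a e^{bx} / (1 + (a gamma / b)(e^{bx} - 1)) + c`. For `gamma = 0` this
#' reduces exactly to the homogeneous Gompertz-Makeham hazard. The
#' age-dependent part is sigmoid in age and bounded above by `b / gamma`
#' (the mortality plateau).
#'
#' @inheritParams ggm_hazard
#' @return Hazard rate(s), per year.
#' @examples
#' p <- ggm_params(a = 0.02, b = 0.1, c = 0.005, gamma = 0.2)
#' ggm_marginal_hazard(c(0, 40, 80), p)
#' @export
ggm_marginal_hazard <- function(x, params) {
  stopifnot(inherits(params, "ggm_params"), is.numeric(x))
  if (any(x < 0)) stop("model age `x` must be >= 0", call. = FALSE)
  ebx <- exp(params$b * x)
  params$a * ebx / (1 + (params$a * params$gamma / params$b) * (ebx - 1)) +
    params$c
}

#' Cumulative marginal hazard of the GGM model
#'
#' Closed-form integral of [ggm_marginal_hazard()] from model age 0 to `x`:
#' `log1p((a gamma / b)(e^{bx} - 1)) / gamma + c x`, with the `gamma -> 0`
#' limit `(a / b)(e^{bx} - 1) + c x`. Population survivorship to model age
#' `x` is `exp(-ggm_cumulative_hazard(x, params))`.
#'
#' @inheritParams ggm_hazard
#' @return Cumulative hazard(s), dimensionless.
#' @export
ggm_cumulative_hazard <- function(x, params) {
  stopifnot(inherits(params, "ggm_params"), is.numeric(x))
  if (any(x < 0)) stop("model age `x` must be >= 0", call. = FALSE)
  grow <- expm1(params$b * x) # e^{bx} - 1, accurate near 0
  if (params$gamma > 0) {
    log1p(params$a * params$gamma / params$b * grow) / params$gamma +
      params$c * x
  } else {
    params$a / params$b * grow + params$c * x
  }
}

#' Baseline age-specific mortality vector
#'
#' The age-dependent baseline part of the hazard evaluated on the model's
#' discrete age grid: entry `j` (for `j = 1..omega`) is `a * exp((j-1) * b)`,
#' i.e. the Gompertz schedule at model ages `0 .. omega - 1`. Frailty group
#' `i` experiences hazard `z_i * mu0 + c`.
#'
#' @param params A [ggm_params()] object.
#' @param omega Number of discrete age classes (>= 1); 150 by default, enough
#'   that survivorship beyond the last class is negligible for human-range
#'   parameters.
#'
#' @return Numeric vector of length `omega`.
#' @export
baseline_mortality_vector <- function(params, omega = 150) {
  stopifnot(inherits(params, "ggm_params"))
  if (!is.numeric(omega) || length(omega) != 1L || omega < 1) {
    stop("`omega` must be a single integer >= 1", call. = FALSE)
  }
  params$a * exp(params$b * (seq_len(omega) - 1))
}

#' Re-anchor GGM parameters to a later starting age
#'
#' Shifts the model origin forward by conditioning on survival to
#' `new_start_age`. Under gamma frailty, within-cohort selection preserves
#' the gamma shape: the survivors' frailty, renormalized to mean 1, is again
#' gamma with the same mean-1 variance `gamma`, while the baseline level
#' absorbs both the Gompertz growth and the selection-induced decline in
#' mean frailty: `a' = a e^{bk} / (1 + (a gamma / b)(e^{bk} - 1))` for a
#' shift of `k` years (which is the age-dependent part of the marginal
#' hazard at the new origin); `b`, `c` and `gamma` are unchanged.
#'
#' @param params A [ggm_params()] object.
#' @param new_start_age New starting age (>= `params$start_age`).
#' @return A [ggm_params()] object anchored at `new_start_age`.
#' @export
reanchor_ggm_params <- function(params, new_start_age) {
  stopifnot(inherits(params, "ggm_params"))
  k <- new_start_age - params$start_age
  if (k < 0) stop("`new_start_age` must be >= params$start_age", call. = FALSE)
  ebk <- exp(params$b * k)
  a_new <- params$a * ebk /
    (1 + (params$a * params$gamma / params$b) * (ebk - 1))
  ggm_params(a = a_new, b = params$b, c = params$c, gamma = params$gamma,
             start_age = new_start_age)
}
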