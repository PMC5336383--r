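# Seed handling: simulations accept an explicit seed and restore the caller's
# RNG state afterwards, so generating data never perturbs outer randomness.
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic HMD-style cohort mortality table
#'
#' Simulates the generative model behind the Poisson likelihood used for
#' fitting: exposures follow deterministic cohort survivorship under the
#' marginal GGM hazard, with person-years at age `x` approximated by the
#' trapezoid of survivorship at `x` and `x + 1`; death counts are drawn as
#' `D(x) ~ Poisson(E(x) * mu(x + 1/2))` with `mu` the marginal hazard
#' evaluated at mid-interval (the central-death-rate convention for one-year
#' age bins).
#'
#' @param params A [ggm_params()] object; `params$start_age` is the first
#'   tabulated age.
#' @param n0 Initial cohort size at the starting age (> 0).
#' @param n_ages Number of one-year age classes to tabulate (>= 2).
#' @param cohort,sex Labels stored in the table.
#' @param seed Optional integer seed; given the seed the table is
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return A mortality tibble (`cohort`, `sex`, `age`, `deaths`, `exposure`)
#'   carrying a `generator` attribute with the parameters and seed.
#' @examples
#' p <- ggm_params(0.02, 0.1, 0.005, 0.2, start_age = 40)
#' generate_poisson_cohort(p, n0 = 1e5, n_ages = 10, seed = 1)
#' @export
generate_poisson_cohort <- function(params, n0 = 1e6, n_ages = 70,
                                    cohort = "synthetic", sex = "total",
                                    seed = NULL) {
  stopifnot(inherits(params, "ggm_params"))
  if (!is.numeric(n0) || n0 <= 0) stop("`n0` must be > 0", call. = FALSE)
  if (!is.numeric(n_ages) || n_ages < 2) {
    stop("`n_ages` must be >= 2", call. = FALSE)
  }
  n_ages <- as.integer(n_ages)
  x <- 0:(n_ages - 1)
  lx <- exp(-ggm_cumulative_hazard(0:n_ages, params))
  exposure <- n0 * (lx[-length(lx)] + lx[-1]) / 2
  rate <- exposure * ggm_marginal_hazard(x + 0.5, params)
  deaths <- with_sim_seed(seed, stats::rpois(n_ages, rate))
  out <- tibble::tibble(
    cohort = cohort, sex = sex,
    age = params$start_age + x,
    deaths = as.numeric(deaths),
    exposure = exposure
  )
  attr(out, "generator") <- list(
    a = params$a, b = params$b, c = params$c, gamma = params$gamma,
    start_age = params$start_age, n0 = n0,
    seed = if (is.null(seed)) NA else seed
  )
  out
}

#' Simulate individual lifetimes from the discrete age-by-frailty chain
#'
#' Monte Carlo oracle for the matrix model: each individual draws a frailty
#' class from the mixing distribution, then survives each one-year age class
#' `j` with probability `exp(-mu(z_i, j - 1))`, exactly the subdiagonal
#' survival probabilities of the age-by-frailty projection matrix. The last
#' age class is terminal (certain death), so lifetimes count age classes
#' attained, in `1 .. omega`, including the starting class.
#'
#' @param params A [ggm_params()] object.
#' @param frailty A [discretize_frailty()] grid.
#' @param n Number of individuals (>= 1).
#' @param omega Number of age classes (default 150).
#' @param seed Optional integer seed (reproducible, RNG state restored).
#'
#' @return A tibble with one row per individual: `frailty_class`, `z`, and
#'   `lifetime` (age classes attained).
#' @export
simulate_lifetimes <- function(params, frailty, n, omega = 150, seed = NULL) {
  stopifnot(inherits(params, "ggm_params"), inherits(frailty, "frailty_grid"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(omega) || omega < 2) stop("`omega` must be >= 2", call. = FALSE)
  n <- as.integer(n)
  omega <- as.integer(omega)
  # survival probabilities p[i, j]: class z_i survives age class j (ages 0..omega-2)
  p <- outer(frailty$z, 0:(omega - 2),
             function(z, x) exp(-ggm_hazard(x, z, params)))
  with_sim_seed(seed, {
    cls <- sample.int(frailty$g, n, replace = TRUE, prob = frailty$pi)
    lifetime <- rep.int(omega, n) # survivors of every transition die at omega
    alive <- seq_len(n)
    for (j in seq_len(omega - 1)) {
      died <- stats::runif(length(alive)) >= p[cbind(cls[alive], j)]
      lifetime[alive[died]] <- j
      alive <- alive[!died]
      if (length(alive) == 0) break
    }
    tibble::tibble(frailty_class = cls, z = frailty$z[cls], lifetime = lifetime)
  })
}
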