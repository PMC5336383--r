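#' Fundamental matrix of the absorbing age-by-frailty chain
#'
#' `N_tilde = (I - U_tilde)^(-1)`. Column `j` holds the expected number of
#' visits to each transient state for an individual starting in state `j`
#' (column orientation); because age always advances, no state is revisited
#' and the diagonal is 1. The chain is nilpotent, so the inverse equals the
#' finite Neumann series `I + U_tilde + U_tilde^2 + ...`.
#'
#' @param model An `age_frailty_model`, or any substochastic nilpotent
#'   transient matrix.
#' @return The fundamental matrix (a `Matrix` sparse matrix).
#' @export
fundamental_matrix <- function(model) {
  U <- transient_matrix(model)
  n <- nrow(U)
  A <- Matrix::Diagonal(n) - U
  N <- tryCatch(Matrix::solve(A, Matrix::Diagonal(n)),
                error = function(e) {
                  stop("(I - U_tilde) is singular: transient matrix is not ",
                       "substochastic-nilpotent", call. = FALSE)
                })
  N
}

transient_matrix <- function(model) {
  if (inherits(model, "age_frailty_model")) {
    model$U_tilde
  } else if (is.matrix(model) || inherits(model, "Matrix")) {
    methods::as(Matrix::Matrix(model, sparse = TRUE), "generalMatrix")
  } else {
    stop("expected an age_frailty_model or a matrix", call. = FALSE)
  }
}

#' Moments of remaining longevity for every age-by-frailty state
#'
#' Longevity is the number of age classes visited before absorption (death),
#' counting the starting class. From the fundamental matrix `N`:
#' first moments `eta1 = t(1' N)`, second moments `eta2 = t(eta1' (2N - I))`,
#' and variance `V = eta2 - eta1 * eta1`.
#'
#' Given an `age_frailty_model` the moments are computed by two sparse
#' triangular solves against `(I - U_tilde)'` without forming the fundamental
#' matrix, which keeps the full-size model (`omega = 150`, `g = 200`;
#' 30 000 states) fast and memory-light. Given a fundamental matrix the
#' closed-form expressions above are applied directly.
#'
#' @param x An `age_frailty_model` or a fundamental matrix.
#' @return A list with numeric vectors `eta1`, `eta2`, `variance`, each of
#'   length `omega * g`, in the frailty-within-age ordering.
#' @export
longevity_moments <- function(x) {
  if (inherits(x, "age_frailty_model")) {
    n <- nrow(x$U_tilde)
    At <- Matrix::t(Matrix::Diagonal(n) - x$U_tilde)
    eta1 <- as.numeric(Matrix::solve(At, rep(1, n)))
    eta2 <- 2 * as.numeric(Matrix::solve(At, eta1)) - eta1
  } else {
    N <- transient_matrix(x) # here: the fundamental matrix itself
    eta1 <- as.numeric(Matrix::colSums(N))
    eta2 <- as.numeric(Matrix::crossprod(N, eta1)) * 2 - eta1
  }
  v <- eta2 - eta1^2
  v[v < 0 & v > -1e-9] <- 0 # clamp roundoff on deterministic states
  list(eta1 = eta1, eta2 = eta2, variance = v)
}

#' Extract per-frailty-group moments for the first age class
#'
#' Applies `(e_1' (x) I_g)` to a full state vector: under the
#' frailty-within-age ordering the first age block is simply the first `g`
#' entries.
#'
#' @param eta1,variance Numeric vectors of length `omega * g` (from
#'   [longevity_moments()]).
#' @param omega,g Model dimensions.
#' @return A list with `means` and `variances`, each of length `g`.
#' @export
extract_age1_groups <- function(eta1, variance, omega, g) {
  if (length(eta1) != omega * g || length(variance) != omega * g) {
    stop("vectors must have length omega * g = ", omega * g, call. = FALSE)
  }
  list(means = eta1[seq_len(g)], variances = variance[seq_len(g)])
}

#' Decompose the variance of longevity into stochastic and frailty components
#'
#' Treats longevity at the first age class as a mixture over frailty groups
#' with mixing weights `pi` and applies the law of total variance:
#' the within-group component `V_within = pi' V_groups` is variance due to
#' individual stochasticity; the between-group component
#' `V_between = pi'(E_groups^2) - (pi' E_groups)^2` is variance due to
#' heterogeneous frailty; their sum is the total variance.
#'
#' @param group_means,group_variances Numeric vectors of length `g`
#'   (per-frailty-group mean and variance of longevity).
#' @param pi Mixing probability vector of length `g` (must sum to 1; no
#'   silent renormalization).
#' @return An object of class `longevity_decomposition` with fields
#'   `group_means`, `group_variances`, `pi`, `mixture_mean`, `v_total`,
#'   `v_within`, `v_between`, and `fraction_heterogeneity`
#'   (`v_between / v_total`, `NaN` when the total variance is zero).
#' @examples
#' d <- decompose_variance(c(2, 4), c(0, 0), c(0.5, 0.5))
#' d$v_between # 1
#' @export
decompose_variance <- function(group_means, group_variances, pi) {
  g <- length(pi)
  if (length(group_means) != g || length(group_variances) != g) {
    stop("`group_means`, `group_variances` and `pi` must have equal length",
         call. = FALSE)
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("`pi` must be a probability vector summing to 1", call. = FALSE)
  }
  if (any(group_variances < 0)) {
    stop("group variances must be >= 0", call. = FALSE)
  }
  mixture_mean <- sum(pi * group_means)
  v_within <- sum(pi * group_variances)
  v_between <- max(0, sum(pi * group_means^2) - mixture_mean^2)
  v_total <- v_within + v_between
  structure(
    list(group_means = group_means, group_variances = group_variances,
         pi = pi, mixture_mean = mixture_mean,
         v_total = v_total, v_within = v_within, v_between = v_between,
         fraction_heterogeneity = if (v_total > 0) v_between / v_total
                                  else NaN),
    class = "longevity_decomposition"
  )
}

#' @export
print.longevity_decomposition <- function(x, ...) {
  cat("<longevity_decomposition>\n")
  cat(sprintf("  mean longevity (age classes incl. start): %.4f\n",
              x$mixture_mean))
  cat(sprintf("  V_total = %.4f = V_within %.4f + V_between %.4f\n",
              x$v_total, x$v_within, x$v_between))
  cat(sprintf("  fraction due to heterogeneous frailty: %.4f\n",
              x$fraction_heterogeneity))
  invisible(x)
}

#' Tidy and glance methods for longevity decompositions
#'
#' `tidy()` returns one row per frailty group (weight, mean, variance);
#' `glance()` a one-row summary with the variance components. Means are
#' reported both as Markov-chain visit counts (`mean_age_classes`, counting
#' the starting class) and as remaining years beyond the starting age
#' (`mean_remaining`, the visit count minus one); variances are invariant to
#' that shift.
#'
#' @param x A `longevity_decomposition` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.longevity_decomposition <- function(x, ...) {
  tibble::tibble(
    group = seq_along(x$pi),
    weight = x$pi,
    mean = x$group_means,
    variance = x$group_variances
  )
}

#' @rdname tidy.longevity_decomposition
#' @export
glance.longevity_decomposition <- function(x, ...) {
  tibble::tibble(
    mean_age_classes = x$mixture_mean,
    mean_remaining = x$mixture_mean - 1,
    v_total = x$v_total,
    v_within = x$v_within,
    v_between = x$v_between,
    fraction_heterogeneity = x$fraction_heterogeneity
  )
}

#' Full matrix-model decomposition from GGM parameters
#'
#' Convenience pipeline for one parameter set: discretize the frailty
#' distribution (applying the degeneracy rule), build the age-by-frailty
#' projection matrix, compute longevity moments, extract the first age
#' class, and decompose its variance.
#'
#' @param params A [ggm_params()] object.
#' @param frailty Optional pre-built [discretize_frailty()] grid; by default
#'   built from `params$gamma` with the `g`, `q_min`, `q_max`,
#'   `degeneracy_threshold` arguments.
#' @param omega Number of age classes.
#' @inheritParams discretize_frailty
#' @return A `longevity_decomposition` object.
#' @examples
#' p <- ggm_params(0.02, 0.1, 0.005, 0.2, start_age = 40)
#' glance(decompose_longevity(p, g = 50, omega = 110))
#' @export
decompose_longevity <- function(params, frailty = NULL, omega = 150, g = 200,
                                q_min = 1e-5, q_max = 0.9999,
                                degeneracy_threshold = 1e-5) {
  stopifnot(inherits(params, "ggm_params"))
  if (is.null(frailty)) {
    frailty <- discretize_frailty(params$gamma, g = g, q_min = q_min,
                                  q_max = q_max,
                                  degeneracy_threshold = degeneracy_threshold)
  }
  model <- build_projection_matrix(params, frailty, omega = omega)
  mom <- longevity_moments(model)
  groups <- extract_age1_groups(mom$eta1, mom$variance, omega, frailty$g)
  decompose_variance(groups$means, groups$variances, frailty$pi)
}

#' Monte Carlo decomposition of longevity variance
#'
#' Independent simulation-based counterpart of [decompose_longevity()]:
#' simulates `n` individual lifetimes with known frailty labels via
#' [simulate_lifetimes()] and computes the empirical within/between
#' decomposition by group, using the empirical class frequencies as weights
#' and the population (divide-by-n) variance within groups so the law of
#' total variance holds exactly in-sample.
#'
#' @inheritParams simulate_lifetimes
#' @return A `longevity_decomposition` object (empirical); classes never
#'   sampled get weight 0 and degenerate moments.
#' @export
monte_carlo_decomposition <- function(params, frailty, omega = 150, n = 1e5,
                                      seed = NULL) {
  sims <- simulate_lifetimes(params, frailty, n = n, omega = omega,
                             seed = seed)
  empirical_decomposition(sims$lifetime, sims$frailty_class, frailty$g)
}

# within/between decomposition of values grouped by integer labels 1..g,
# empirical weights, population variances (law of total variance exact)
empirical_decomposition <- function(values, labels, g) {
  n <- length(values)
  counts <- tabulate(labels, nbins = g)
  sums <- vapply(seq_len(g), function(i) sum(values[labels == i]), 0)
  sq <- vapply(seq_len(g), function(i) sum(values[labels == i]^2), 0)
  means <- ifelse(counts > 0, sums / counts, 0)
  vars <- ifelse(counts > 0, sq / pmax(counts, 1) - means^2, 0)
  vars <- pmax(vars, 0)
  decompose_variance(means, vars, counts / n)
}
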