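#' Discretize the gamma frailty distribution into classes
#'
#' Approximates the mean-1 gamma frailty distribution (shape `1/gamma`, scale
#' `gamma`, so mean 1 and variance `gamma`) by `g` discrete frailty values
#' with mixing weights. Nodes are logarithmically spaced between the `q_min`
#' and `q_max` quantiles of the distribution; each node receives the gamma
#' probability mass of its bin, with bin boundaries at the geometric midpoints
#' between adjacent nodes and the first/last bins extended to 0 and infinity
#' so that total probability is conserved. The node vector is then rescaled so
#' the discretized mean is exactly 1, preventing discretization bias from
#' shifting the baseline hazard.
#'
#' When `gamma < degeneracy_threshold` heterogeneity is treated as absent and
#' a single class with `z = 1` is returned.
#'
#' @param gamma Variance of the mean-1 gamma frailty distribution (>= 0).
#' @param g Number of frailty classes (>= 1); 200 by default.
#' @param q_min,q_max Lower and upper gamma-cdf bounds for the node range
#'   (defaults `1e-5` and `0.9999`).
#' @param degeneracy_threshold Variance below which the distribution is
#'   collapsed to the single class `z = 1` (default `1e-5`).
#'
#' @return An object of class `frailty_grid` with elements `z` (strictly
#'   increasing frailty values), `pi` (mixing weights summing to 1), `g`, and
#'   `gamma`.
#' @examples
#' fr <- discretize_frailty(0.2)
#' sum(fr$pi * fr$z)            # exactly 1
#' sum(fr$pi * fr$z^2) - 1      # close to 0.2
#' @export
discretize_frailty <- function(gamma, g = 200, q_min = 1e-5, q_max = 0.9999,
                               degeneracy_threshold = 1e-5) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  if (!is.numeric(g) || length(g) != 1L || g < 1) {
    stop("`g` must be a single integer >= 1", call. = FALSE)
  }
  g <- as.integer(g)
  if (!(q_min > 0 && q_min < q_max && q_max < 1)) {
    stop("need 0 < q_min < q_max < 1", call. = FALSE)
  }
  if (gamma < degeneracy_threshold || g == 1L) {
    return(new_frailty_grid(z = 1, pi = 1, gamma = gamma))
  }
  shape <- 1 / gamma
  z <- exp(seq(log(stats::qgamma(q_min, shape = shape, scale = gamma)),
               log(stats::qgamma(q_max, shape = shape, scale = gamma)),
               length.out = g))
  # bin edges: geometric midpoints, outer bins extended to 0 and +Inf
  edges <- c(0, sqrt(z[-g] * z[-1]), Inf)
  pi <- diff(stats::pgamma(edges, shape = shape, scale = gamma))
  z <- z / sum(pi * z)
  new_frailty_grid(z = z, pi = pi, gamma = gamma)
}

new_frailty_grid <- function(z, pi, gamma) {
  structure(
    list(z = z, pi = pi, g = length(z), gamma = gamma),
    class = "frailty_grid"
  )
}

#' @export
print.frailty_grid <- function(x, ...) {
  cat(sprintf("<frailty_grid> g = %d classes, gamma = %.6g\n", x$g, x$gamma))
  cat(sprintf("  z in [%.4g, %.4g], discretized mean %.8f, variance %.6g\n",
              min(x$z), max(x$z), sum(x$pi * x$z),
              sum(x$pi * x$z^2) - sum(x$pi * x$z)^2))
  invisible(x)
}

#' @rdname discretize_frailty
#' @param x A `frailty_grid` object.
#' @param ... Unused.
#' @export
tidy.frailty_grid <- function(x, ...) {
  tibble::tibble(class = seq_len(x$g), z = x$z, weight = x$pi)
}
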