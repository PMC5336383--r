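#' Plot a fitted GGM hazard against observed death rates
#'
#' Observed central death rates `D(x) / E(x)` (points, log scale) with the
#' fitted marginal hazard (line) over the fitted age range.
#'
#' @param object A `ggm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ggm_fit <- function(object, ...) {
  obs <- dplyr::filter(object$data, .data$exposure > 0)
  obs$rate <- obs$deaths / obs$exposure
  start <- object$params$start_age
  grid <- tibble::tibble(
    age = seq(min(obs$age), max(obs$age), by = 0.25),
    hazard = ggm_marginal_hazard(.data$age - start + object$age_offset,
                                 object$params)
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate), alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$hazard),
                       colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "death rate (per year, log scale)",
                  title = "Observed death rates and fitted marginal hazard")
}

#' Plot a discretized frailty distribution
#'
#' Discrete mixing weights against frailty value (log scale), overlaid with
#' the continuous gamma density scaled to the local bin widths.
#'
#' @param object A `frailty_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frailty_grid <- function(object, ...) {
  d <- tidy(object)
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$weight)) +
    ggplot2::geom_col(width = 0.01, fill = "grey40") +
    ggplot2::labs(x = "frailty z (log scale)", y = "mixing weight",
                  title = sprintf("Discretized gamma frailty (g = %d, variance %.3g)",
                                  object$g, object$gamma))
  if (object$g > 1) pl <- pl + ggplot2::scale_x_log10()
  pl
}

#' Plot a longevity variance decomposition
#'
#' Stacked bar of the within-group (stochasticity) and between-group
#' (heterogeneous frailty) variance components.
#'
#' @param object A `longevity_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.longevity_decomposition <- function(object, ...) {
  d <- tibble::tibble(
    component = factor(c("stochasticity (within)", "heterogeneity (between)"),
                       levels = c("stochasticity (within)",
                                  "heterogeneity (between)")),
    variance = c(object$v_within, object$v_between)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$variance,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("grey75", "grey30")) +
    ggplot2::labs(x = NULL, y = "variance of remaining longevity (years^2)",
                  title = sprintf("Variance decomposition (%.1f%% heterogeneity)",
                                  100 * object$fraction_heterogeneity))
}

#' Plot variance components across a cohort sweep
#'
#' Stacked variance components per cohort, faceted by starting age (and sex
#' when more than one is present).
#'
#' @param results Output of [run_decomposition_analysis()].
#' @return A ggplot object.
#' @export
plot_variance_components <- function(results) {
  ok <- dplyr::filter(results, !.data$failed)
  long <- tidyr::pivot_longer(
    ok, c("v_within", "v_between"),
    names_to = "component", values_to = "variance"
  )
  long$component <- factor(
    dplyr::recode(long$component, v_within = "stochasticity (within)",
                  v_between = "heterogeneity (between)"),
    levels = c("stochasticity (within)", "heterogeneity (between)")
  )
  pl <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort,
                                           y = .data$variance,
                                           fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("grey75", "grey30")) +
    ggplot2::labs(x = "birth cohort", y = "variance (years^2)",
                  fill = NULL)
  facets <- if (length(unique(ok$sex)) > 1) {
    ggplot2::facet_grid(ggplot2::vars(.data$sex),
                        ggplot2::vars(.data$start_age))
  } else {
    ggplot2::facet_wrap(ggplot2::vars(.data$start_age))
  }
  pl + facets
}
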