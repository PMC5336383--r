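#' Analysis configuration
#'
#' Collects the knobs of the full decomposition pipeline in one validated
#' object. Defaults follow the reference study conditions: starting ages
#' 40/50/60/70, 200 frailty classes bounded by the gamma-cdf quantiles
#' `1e-5` and `0.9999`, 150 age classes, and a frailty-variance degeneracy
#' threshold of `1e-5`.
#'
#' @param start_ages Integer vector of starting ages to analyse.
#' @param g,omega,q_min,q_max,degeneracy_threshold See
#'   [discretize_frailty()] and [decompose_longevity()].
#' @param bounds,control,age_offset See [fit_ggm()].
#' @param seed Integer master seed for the whole run.
#' @param period_bins Tibble of non-overlapping cohort bins with columns
#'   `label`, `first_cohort`, `last_cohort` (see [default_period_bins()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(start_ages = c(40, 50, 60, 70),
                            g = 200, omega = 150,
                            q_min = 1e-5, q_max = 0.9999,
                            degeneracy_threshold = 1e-5,
                            bounds = list(a = c(1e-6, 1), b = c(1e-3, 1),
                                          c = c(0, 0.5), gamma = c(0, 5)),
                            control = de_control(),
                            age_offset = 0.5,
                            seed = 1,
                            period_bins = default_period_bins()) {
  stopifnot(length(start_ages) >= 1, all(start_ages >= 0), g >= 1, omega >= 2)
  bins <- tibble::as_tibble(period_bins)
  if (nrow(bins) > 1) {
    ord <- order(bins$first_cohort)
    if (any(bins$first_cohort[ord][-1] <= bins$last_cohort[ord][-nrow(bins)])) {
      stop("period bins must be non-overlapping", call. = FALSE)
    }
  }
  structure(
    list(start_ages = as.integer(start_ages), g = as.integer(g),
         omega = as.integer(omega), q_min = q_min, q_max = q_max,
         degeneracy_threshold = degeneracy_threshold, bounds = bounds,
         control = control, age_offset = age_offset,
         seed = as.integer(seed), period_bins = bins),
    class = "analysis_config"
  )
}

#' Default historical period bins
#'
#' The three birth-cohort periods used when averaging heterogeneity
#' fractions over cohorts: 1751-1815, 1816-1871, 1872-1899.
#'
#' @return A tibble with columns `label`, `first_cohort`, `last_cohort`.
#' @export
default_period_bins <- function() {
  tibble::tibble(
    label = c("1751-1815", "1816-1871", "1872-1899"),
    first_cohort = c(1751, 1816, 1872),
    last_cohort = c(1815, 1871, 1899)
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [analysis_config()]
#' (`start_ages`, `g`, `omega`, `q_min`, `q_max`, `degeneracy_threshold`,
#' `seed`, `age_offset`, `bounds` as a mapping of parameter to `[lo, hi]`,
#' `optimizer` as a mapping of [de_control()] arguments, and `period_bins`
#' as a list of `{label, first_cohort, last_cohort}` records). Unspecified
#' keys keep their defaults.
#'
#' @param path Path to the YAML file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("start_ages", "g", "omega", "q_min", "q_max",
                          "degeneracy_threshold", "seed", "age_offset"))]
  if (!is.null(raw$bounds)) {
    args$bounds <- utils::modifyList(
      list(a = c(1e-6, 1), b = c(1e-3, 1), c = c(0, 0.5), gamma = c(0, 5)),
      lapply(raw$bounds, as.numeric)
    )
  }
  if (!is.null(raw$optimizer)) {
    args$control <- do.call(de_control, raw$optimizer)
  }
  if (!is.null(raw$period_bins)) {
    args$period_bins <- dplyr::bind_rows(lapply(raw$period_bins,
                                                tibble::as_tibble))
  }
  do.call(analysis_config, args)
}

#' Run the full variance-decomposition pipeline over cohort tables
#'
#' For every (cohort, sex) series in `data` and every starting age: fit the
#' GGM model by Poisson maximum likelihood, discretize the fitted frailty
#' distribution (collapsing to a single class when the fitted variance falls
#' below the degeneracy threshold), build the age-by-frailty Markov chain,
#' and decompose the variance of remaining longevity. Per-series fit
#' failures are reported as rows flagged `failed = TRUE` (with a message),
#' never as an aborted sweep. The run is deterministic given the config
#' seed: each (series, start age) task derives its own sub-seed.
#'
#' @param data A mortality table covering one or more (cohort, sex) series.
#' @param config An [analysis_config()] object.
#' @return A tibble with one row per (cohort, sex, start_age): fitted
#'   parameters, fit diagnostics, whether the degeneracy rule fired, and the
#'   decomposition (`mean_remaining`, `v_total`, `v_within`, `v_between`,
#'   `fraction_heterogeneity`).
#' @export
run_decomposition_analysis <- function(data, config = analysis_config()) {
  data <- validate_mortality_table(data)
  stopifnot(inherits(config, "analysis_config"))
  series <- dplyr::distinct(data, .data$cohort, .data$sex)
  tasks <- tidyr::crossing(series, start_age = config$start_ages)
  rows <- purrr::pmap(
    list(tasks$cohort, tasks$sex, tasks$start_age, seq_len(nrow(tasks))),
    function(cohort, sex, start_age, task_id) {
      tab <- data[data$cohort == cohort & data$sex == sex, ]
      sub_seed <- (config$seed + 7919L * task_id) %% .Machine$integer.max
      tryCatch({
        fit <- fit_ggm(tab, start_age = start_age, bounds = config$bounds,
                       control = config$control,
                       age_offset = config$age_offset, seed = sub_seed)
        dec <- decompose_longevity(
          fit$params, omega = config$omega, g = config$g,
          q_min = config$q_min, q_max = config$q_max,
          degeneracy_threshold = config$degeneracy_threshold
        )
        degenerate <- fit$params$gamma < config$degeneracy_threshold
        message(sprintf(
          "cohort %s %s start %d: a=%.4g b=%.4g c=%.4g gamma=%.4g%s",
          cohort, sex, start_age, fit$params$a, fit$params$b, fit$params$c,
          fit$params$gamma,
          if (degenerate) " [degeneracy rule fired]" else ""))
        tibble::tibble(
          cohort = cohort, sex = sex, start_age = start_age,
          failed = FALSE, converged = fit$converged,
          degenerate = degenerate,
          a = fit$params$a, b = fit$params$b, c = fit$params$c,
          gamma = fit$params$gamma,
          log_likelihood = fit$log_likelihood,
          n_ages_used = fit$n_ages_used,
          mean_remaining = dec$mixture_mean - 1,
          v_total = dec$v_total, v_within = dec$v_within,
          v_between = dec$v_between,
          fraction_heterogeneity = dec$fraction_heterogeneity
        )
      }, error = function(e) {
        message(sprintf("cohort %s %s start %d: FAILED (%s)",
                        cohort, sex, start_age, conditionMessage(e)))
        tibble::tibble(
          cohort = cohort, sex = sex, start_age = start_age,
          failed = TRUE, converged = FALSE, degenerate = NA,
          a = NA_real_, b = NA_real_, c = NA_real_, gamma = NA_real_,
          log_likelihood = NA_real_, n_ages_used = NA_integer_,
          mean_remaining = NA_real_, v_total = NA_real_,
          v_within = NA_real_, v_between = NA_real_,
          fraction_heterogeneity = NA_real_
        )
      })
    }
  )
  dplyr::bind_rows(rows)
}

#' Average heterogeneity fractions over cohorts within historical periods
#'
#' Assigns each result row to the period bin containing its cohort (cohort
#' labels must be interpretable as years) and reports the arithmetic mean of
#' `fraction_heterogeneity` per (grouping, start_age, period). Bins with no
#' cohorts appear with `n_cohorts = 0` and `NA` mean, never a silent zero.
#' If the results carry a `country` column it is included in the grouping.
#'
#' @param results Output of [run_decomposition_analysis()] (failed rows are
#'   dropped with a message).
#' @param period_bins Tibble with `label`, `first_cohort`, `last_cohort`.
#' @return A tibble with one row per (grouping, start_age, period).
#' @export
summarize_periods <- function(results, period_bins = default_period_bins()) {
  stopifnot(nrow(results) >= 1)
  bins <- tibble::as_tibble(period_bins)
  if (any(results$failed)) {
    message(sum(results$failed), " failed row(s) excluded from period means")
    results <- results[!results$failed, ]
  }
  results$cohort_year <- suppressWarnings(as.numeric(results$cohort))
  if (anyNA(results$cohort_year)) {
    stop("cohort labels must be interpretable as years for period binning",
         call. = FALSE)
  }
  group_cols <- intersect(c("country", "sex", "start_age"), names(results))
  groups <- dplyr::distinct(results, dplyr::across(dplyr::all_of(group_cols)))
  grid <- tidyr::crossing(groups, bins)
  assigned <- dplyr::inner_join(
    results, bins,
    by = dplyr::join_by("cohort_year" >= "first_cohort",
                        "cohort_year" <= "last_cohort")
  )
  means <- dplyr::summarise(
    dplyr::group_by(assigned,
                    dplyr::across(dplyr::all_of(c(group_cols, "label")))),
    n_cohorts = dplyr::n(),
    mean_fraction = mean(.data$fraction_heterogeneity),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, means, by = c(group_cols, "label"))
  out$n_cohorts[is.na(out$n_cohorts)] <- 0L
  dplyr::arrange(
    dplyr::rename(out, period = "label"),
    dplyr::across(dplyr::all_of(c(group_cols, "first_cohort")))
  )
}

#' Write pipeline results to a tab-separated file
#'
#' One row per (cohort, sex, start_age) with the fitted parameters and
#' variance components; the canonical serialization of a decomposition
#' sweep.
#'
#' @param results Output of [run_decomposition_analysis()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
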