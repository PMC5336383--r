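test_that("log-likelihood matches direct evaluation and is additive", {
  # single age, D = 2, E = 10, mu = 0.1: 2 log(0.1) - 1
  # params chosen so the marginal hazard at model age 0 is exactly 0.1
  p <- ggm_params(a = 0.08, b = 0.1, c = 0.02, gamma = 0.5)
  tab1 <- tibble::tibble(cohort = "t", sex = "total", age = 40, deaths = 2,
                         exposure = 10)
  expect_equal(ggm_loglik(p, tab1, start_age = 40),
               2 * log(0.1) - 1, tolerance = 1e-12)
  expect_equal(2 * log(0.1) - 1, -5.605170, tolerance = 1e-6)
  # all deaths zero: only the exposure term remains
  p2 <- test_params()
  tab0 <- tibble::tibble(cohort = "t", sex = "total", age = 40:49,
                         deaths = 0, exposure = 100)
  expect_equal(ggm_loglik(p2, tab0, start_age = 40),
               -sum(100 * ggm_marginal_hazard(0:9, p2)))
  # additivity over disjoint age ranges (contiguous within each series)
  tabA <- tibble::tibble(cohort = "A", sex = "total", age = 40:44,
                         deaths = c(3, 1, 4, 1, 5), exposure = 100)
  tabB <- tibble::tibble(cohort = "B", sex = "total", age = 60:64,
                         deaths = c(2, 7, 1, 8, 2), exposure = 80)
  expect_equal(ggm_loglik(p2, rbind(tabA, tabB), start_age = 40),
               ggm_loglik(p2, tabA, start_age = 40) +
                 ggm_loglik(p2, tabB, start_age = 40))
  # zero-exposure ages are skipped; deaths there are a data error
  tabz <- tabA; tabz$exposure[2] <- 0; tabz$deaths[2] <- 0
  tabA2 <- tabA[-2, ]
  expect_equal(ggm_loglik(p2, tabz, start_age = 40),
               sum(tabA2$deaths *
                     log(ggm_marginal_hazard(tabA2$age - 40, p2)) -
                   tabA2$exposure * ggm_marginal_hazard(tabA2$age - 40, p2)))
  tabz$deaths[2] <- 1
  expect_error(ggm_loglik(p2, tabz, start_age = 40), "zero exposure")
})

test_that("fitting is deterministic given the seed", {
  p <- test_params()
  tab <- generate_poisson_cohort(p, n0 = 1e5, n_ages = 50, seed = 4)
  ctrl <- de_control(n_pop = 15, n_gen = 40)
  f1 <- fit_ggm(tab, start_age = 40, control = ctrl, seed = 77)
  f2 <- fit_ggm(tab, start_age = 40, control = ctrl, seed = 77)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_identical(f1$optimizer_trace, f2$optimizer_trace)
})

test_that("the optimum dominates a coarse grid and the truth", {
  p <- test_params()
  tab <- generate_poisson_cohort(p, n0 = 1e6, n_ages = 70, seed = 15)
  fit <- fit_ggm(tab, start_age = 40, control = test_de_control(), seed = 1)
  expect_true(fit$converged)
  # at least as good as the generating parameters
  expect_gte(fit$log_likelihood,
             ggm_loglik(p, tab, start_age = 40, age_offset = 0.5) - 1e-6)
  # and as every point of a coarse 4-D grid over the box
  grid <- expand.grid(a = c(0.005, 0.02, 0.08), b = c(0.05, 0.1, 0.2),
                      c = c(0, 0.005, 0.05), gamma = c(0, 0.2, 1))
  grid_ll <- apply(grid, 1, function(th) {
    ggm_loglik(ggm_params(th[1], th[2], th[3], th[4], 40), tab,
               start_age = 40, age_offset = 0.5)
  })
  expect_gte(fit$log_likelihood, max(grid_ll))
})

test_that("parameters are recovered from a large synthetic cohort", {
  p <- test_params()
  tab <- generate_poisson_cohort(p, n0 = 1e6, n_ages = 70, seed = 115)
  fit <- fit_ggm(tab, start_age = 40, control = test_de_control(), seed = 15)
  est <- tidy(fit)$estimate
  expect_equal(est[1], p$a, tolerance = 0.1)
  expect_equal(est[2], p$b, tolerance = 0.1)
  expect_equal(est[3], p$c, tolerance = 0.25) # c has ~10% sampling SE here
  expect_equal(est[4], p$gamma, tolerance = 0.25)
})

test_that("homogeneous data yield a frailty variance consistent with zero", {
  p0 <- test_params(gamma = 0)
  tab <- generate_poisson_cohort(p0, n0 = 1e6, n_ages = 70, seed = 205)
  fit <- fit_ggm(tab, start_age = 40, control = test_de_control(), seed = 5)
  # CRLB SE of gamma-hat here is ~5e-3; require consistency with 0 at 3 SE
  expect_lt(fit$params$gamma, 0.02)
  # when the MLE lands on the boundary the degeneracy rule fires downstream
  dec <- decompose_longevity(fit$params)
  if (fit$params$gamma < 1e-5) {
    expect_identical(dec$fraction_heterogeneity, 0)
  } else {
    expect_lt(dec$fraction_heterogeneity, 0.05)
  }
})

test_that("estimator bias shrinks as the cohort grows", {
  p <- test_params()
  err_for <- function(n0, seeds) {
    est <- sapply(seeds, function(s) {
      tab <- generate_poisson_cohort(p, n0 = n0, n_ages = 70, seed = 300 + s)
      f <- fit_ggm(tab, start_age = 40,
                   control = de_control(n_pop = 25, n_gen = 150),
                   seed = s)
      c(f$params$a, f$params$b)
    })
    abs(rowMeans(est) / c(p$a, p$b) - 1)
  }
  small <- err_for(1e4, 1:4)
  large <- err_for(1e6, 1:4)
  expect_true(all(large <= small + 0.02))
  expect_true(all(large < 0.02))
})

test_that("refits at a shifted start age preserve the hazard curve", {
  p <- test_params()
  tab <- generate_poisson_cohort(p, n0 = 1e6, n_ages = 70, seed = 50)
  f40 <- fit_ggm(tab, start_age = 40, control = test_de_control(), seed = 6)
  f50 <- fit_ggm(tab, start_age = 50, control = test_de_control(), seed = 7)
  ages <- seq(50, 100, by = 1)
  mu40 <- ggm_marginal_hazard(ages - 40, f40$params)
  mu50 <- ggm_marginal_hazard(ages - 50, f50$params)
  # curves agree over the common ages even if parameters trade off
  expect_lt(stats::median(abs(mu50 / mu40 - 1)), 0.05)
})
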