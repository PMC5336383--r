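test_that("fundamental matrix: identity, 2x2 closed form, Neumann series", {
  # U = 0: nothing survives, N = I
  expect_equal(as.matrix(fundamental_matrix(matrix(0, 3, 3))), diag(3),
               ignore_attr = TRUE)
  # single class, omega = 2, survival p
  U <- matrix(c(0, 0.3, 0, 0), 2)
  expect_equal(as.matrix(fundamental_matrix(U)),
               matrix(c(1, 0.3, 0, 1), 2), ignore_attr = TRUE)
  # random substochastic age-advancing models: N = sum_t U^t exactly
  set.seed(101)
  for (rep in 1:5) {
    g <- sample(1:5, 1); omega <- sample(2:10, 1)
    fr <- discretize_frailty(runif(1, 0.05, 1), g = g)
    model <- build_projection_matrix(test_params(), fr, omega = omega)
    N <- as.matrix(fundamental_matrix(model))
    neumann <- diag(omega * g)
    term <- diag(omega * g)
    for (t in seq_len(omega)) {
      term <- term %*% as.matrix(model$U_tilde)
      neumann <- neumann + term
    }
    expect_equal(N, neumann, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(diag(N), rep(1, omega * g)) # no state is ever revisited
  }
})

test_that("longevity moments match the Bernoulli closed form", {
  # single class, omega = 2, survival 0.5: absorption time 1 + Bernoulli(0.5)
  U <- matrix(c(0, 0.5, 0, 0), 2)
  mom <- longevity_moments(fundamental_matrix(U))
  expect_equal(mom$eta1, c(1.5, 1))
  expect_equal(mom$variance, c(0.25, 0))
  # deterministic chain: survival 1 everywhere, variance 0 for every state
  omega <- 6
  Udet <- Matrix::sparseMatrix(i = 2:omega, j = 1:(omega - 1), x = 1,
                               dims = c(omega, omega))
  momd <- longevity_moments(fundamental_matrix(Udet))
  expect_equal(momd$eta1, omega:1)
  expect_equal(momd$variance, rep(0, omega))
})

test_that("moments via sparse solves equal moments via the fundamental matrix", {
  p <- test_params()
  fr <- discretize_frailty(0.4, g = 6)
  model <- build_projection_matrix(p, fr, omega = 12)
  from_model <- longevity_moments(model)
  from_N <- longevity_moments(fundamental_matrix(model))
  expect_equal(from_model$eta1, from_N$eta1, tolerance = 1e-12)
  expect_equal(from_model$eta2, from_N$eta2, tolerance = 1e-12)
  expect_equal(from_model$variance, from_N$variance, tolerance = 1e-12)
})

test_that("moments agree with brute-force absorption-time distributions", {
  p <- test_params()
  fr1 <- discretize_frailty(0)
  omega <- 20
  model <- build_projection_matrix(p, fr1, omega = omega)
  mom <- longevity_moments(model)
  bf <- chain_moments_bruteforce(exp(-ggm_hazard(0:(omega - 2), 1, p)))
  expect_equal(mom$eta1[1], bf$mean, tolerance = 1e-12)
  expect_equal(mom$variance[1], bf$var, tolerance = 1e-12)
})

test_that("age-1 extraction is pure index bookkeeping", {
  # g = 2, omega = 2, labelled vector (x11, x21, x12, x22)
  eta1 <- c(1.1, 2.2, 3.3, 4.4)
  v <- c(9, 8, 7, 6)
  out <- extract_age1_groups(eta1, v, omega = 2, g = 2)
  expect_equal(out$means, c(1.1, 2.2))
  expect_equal(out$variances, c(9, 8))
  # g = 1: scalars; constant vectors extract to constants
  out1 <- extract_age1_groups(5:1, rep(2, 5), omega = 5, g = 1)
  expect_equal(out1$means, 5)
  expect_equal(out1$variances, 2)
  expect_error(extract_age1_groups(1:3, 1:3, omega = 2, g = 2), "length")
})

test_that("variance decomposition implements the law of total variance", {
  d <- decompose_variance(c(2, 4), c(0, 0), c(0.5, 0.5))
  expect_equal(d$v_between, 1)
  expect_equal(d$v_within, 0)
  expect_equal(d$fraction_heterogeneity, 1)
  # identical groups: no between-group variance
  d2 <- decompose_variance(c(3, 3, 3), c(1, 1, 1), rep(1 / 3, 3))
  expect_equal(d2$v_between, 0)
  expect_equal(d2$fraction_heterogeneity, 0)
  # homogeneous limit g = 1
  d3 <- decompose_variance(7, 2.5, 1)
  expect_equal(d3$v_between, 0)
  expect_equal(d3$v_total, 2.5)
  # degenerate deterministic chain: fraction is NaN, never 0/0 noise
  d4 <- decompose_variance(c(2, 2), c(0, 0), c(0.5, 0.5))
  expect_true(is.nan(d4$fraction_heterogeneity))
  expect_error(decompose_variance(c(1, 2), c(0, 0), c(0.6, 0.6)),
               "probability")
})

test_that("components sum to the total and outputs are permutation-invariant", {
  p <- test_params()
  fr <- discretize_frailty(0.2, g = 30)
  d <- decompose_longevity(p, frailty = fr, omega = 60)
  expect_equal(d$v_within + d$v_between, d$v_total,
               tolerance = 1e-8 * d$v_total)
  expect_true(d$fraction_heterogeneity >= 0 && d$fraction_heterogeneity <= 1)
  perm <- sample(fr$g)
  fr_perm <- new_frailty_grid_for_test(z = fr$z[perm], pi = fr$pi[perm])
  d_perm <- decompose_variance(d$group_means[perm], d$group_variances[perm],
                               fr$pi[perm])
  expect_equal(d_perm$v_total, d$v_total, tolerance = 1e-12)
  expect_equal(d_perm$v_within, d$v_within, tolerance = 1e-12)
  expect_equal(d_perm$v_between, d$v_between, tolerance = 1e-12)
})

test_that("mixture mean equals summed discrete survivorship", {
  p <- test_params()
  fr <- discretize_frailty(0.25, g = 15)
  omega <- 40
  d <- decompose_longevity(p, frailty = fr, omega = omega)
  # E(visits) = sum over age classes of P(alive at that class)
  l_by_class <- sapply(fr$z, function(z) {
    cumprod(c(1, exp(-ggm_hazard(0:(omega - 2), z, p))))
  })
  expect_equal(d$mixture_mean, sum(l_by_class %*% fr$pi), tolerance = 1e-12)
})

test_that("heterogeneity fraction increases with frailty variance", {
  p0 <- test_params()
  fracs <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(gam) {
    p <- ggm_params(p0$a, p0$b, p0$c, gam, p0$start_age)
    d <- decompose_longevity(p, g = 50, omega = 120)
    c(d$v_between, d$fraction_heterogeneity)
  })
  expect_true(all(diff(fracs[1, ]) > 0)) # v_between strictly increasing
  expect_true(all(diff(fracs[2, ]) > 0)) # fraction strictly increasing
})

test_that("matrix and Monte Carlo decompositions agree at small scale", {
  p <- test_params()
  fr <- discretize_frailty(0.2, g = 20)
  omega <- 80
  dm <- decompose_longevity(p, frailty = fr, omega = omega)
  mc <- monte_carlo_decomposition(p, fr, omega = omega, n = 2e4, seed = 31)
  # crude SE of a variance of n iid values ~ sqrt(2/n) * variance
  se <- sqrt(2 / 2e4) * dm$v_total
  expect_lt(abs(mc$v_total - dm$v_total), 3 * se)
  expect_lt(abs(mc$v_within - dm$v_within), 3 * se)
  expect_lt(abs(mc$fraction_heterogeneity - dm$fraction_heterogeneity), 0.05)
})

test_that("tidy and glance summarise a decomposition", {
  d <- decompose_longevity(test_params(), g = 10, omega = 50)
  td <- tidy(d)
  expect_equal(nrow(td), 10)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)
  gl <- glance(d)
  expect_equal(gl$v_total, d$v_total)
  expect_equal(gl$mean_remaining, gl$mean_age_classes - 1)
})
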