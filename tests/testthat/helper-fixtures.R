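# Canonical human-range parameter set used throughout the suite:
# baseline 0.02/yr at the starting age, 10%/yr Gompertz increase,
# Makeham floor 0.005/yr, frailty variance 0.2, anchored at age 40.
test_params <- function(gamma = 0.2) {
  ggm_params(a = 0.02, b = 0.1, c = 0.005, gamma = gamma, start_age = 40)
}

# reduced optimizer budget for tests; verified seed-robust for the
# canonical generative setting
test_de_control <- function() de_control(n_pop = 30, n_gen = 200)

# brute-force commutation map: position of A[i, j] in vec(A) / vec(t(A))
vec_index <- function(i, j, nrow) (j - 1L) * nrow + i

# hand-built frailty grid (bypasses the gamma-based constructor)
new_frailty_grid_for_test <- function(z, pi) {
  longevar:::new_frailty_grid(z, pi, gamma = sum(pi * z^2) - sum(pi * z)^2)
}

# closed-form moments of absorption time for a pure age chain with
# survival probabilities p[1..omega-1] (certain death at class omega),
# starting from age class 1 and counting the starting class.
chain_moments_bruteforce <- function(p) {
  omega <- length(p) + 1L
  surv <- cumprod(c(1, p))            # P(reach age class j)
  death <- surv * c(1 - p, 1)         # P(lifetime == j)
  m1 <- sum(seq_len(omega) * death)
  m2 <- sum(seq_len(omega)^2 * death)
  list(mean = m1, var = m2 - m1^2, pmf = death)
}
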