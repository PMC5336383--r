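Package: longevar
Title: Decomposing Variance in Longevity into Stochasticity and Heterogeneous Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits the gamma-Gompertz-Makeham (GGM) frailty model to cohort
    death-count/exposure tables by Poisson maximum likelihood, builds an
    age-by-frailty classified absorbing Markov chain via the vec-permutation
    formalism, and decomposes the variance of remaining longevity into a
    within-group component due to individual stochasticity and a between-group
    component due to heterogeneous frailty. Includes a synthetic cohort
    generator emulating Human Mortality Database style tables, a seeded
    differential-evolution fitter, Monte Carlo cross-checks of the matrix
    results, and tidy/ggplot2 interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
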