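#' Vec-permutation (commutation) matrix
#'
#' The permutation matrix `K = K_{g,omega}` satisfying
#' `K %*% vec(A) = vec(t(A))` for every `g x omega` matrix `A`. It converts
#' between the two orderings of the joint age-by-frailty state vector:
#' frailty-within-age blocks (the population vector's convention) and
#' age-within-frailty blocks (on which the block-diagonal survival matrix
#' acts).
#'
#' @param g Number of frailty classes (rows of `A`).
#' @param omega Number of age classes (columns of `A`).
#' @return A sparse `g*omega` square permutation matrix (`Matrix` class).
#' @export
vec_permutation_matrix <- function(g, omega) {
  if (!is.numeric(g) || g < 1 || !is.numeric(omega) || omega < 1) {
    stop("`g` and `omega` must be positive integers", call. = FALSE)
  }
  g <- as.integer(g); omega <- as.integer(omega)
  i <- rep(seq_len(g), each = omega)   # frailty index of each entry of vec(t(A))
  j <- rep(seq_len(omega), times = g)  # age index
  Matrix::sparseMatrix(
    i = (i - 1L) * omega + j, # position in vec(t(A))
    j = (j - 1L) * g + i,     # position in vec(A)
    x = 1,
    dims = c(g * omega, g * omega)
  )
}

#' Age-structured survival matrix for one frailty class
#'
#' The `omega x omega` matrix with age-specific survival probabilities
#' `exp(-mu(z, j - 1))`, `j = 1 .. omega - 1`, on the first subdiagonal and
#' zeros elsewhere: hazards are evaluated at model ages `0 .. omega - 2` for
#' the `omega - 1` transitions, and the last age class has no outgoing
#' survival (certain death).
#'
#' @param z Frailty multiplier (> 0).
#' @param params A [ggm_params()] object.
#' @param omega Number of age classes (>= 2).
#' @return A sparse `omega x omega` matrix.
#' @export
survival_matrix <- function(z, params, omega = 150) {
  stopifnot(inherits(params, "ggm_params"))
  if (!is.numeric(omega) || omega < 2) stop("`omega` must be >= 2", call. = FALSE)
  omega <- as.integer(omega)
  p <- exp(-ggm_hazard(0:(omega - 2), z, params))
  Matrix::sparseMatrix(i = 2:omega, j = 1:(omega - 1), x = p,
                       dims = c(omega, omega))
}

#' Build the age-by-frailty projection matrix
#'
#' Assembles the `omega*g` square transient matrix of the absorbing
#' age-by-frailty Markov chain via the vec-permutation construction: a
#' block-diagonal survival matrix `U = diag(U_1 .. U_g)` acting on
#' age-within-frailty blocks is conjugated into the population vector's
#' frailty-within-age ordering, `U_tilde = t(K) U K`. With fixed frailty (the
#' GGM case) the frailty-transition matrix is the identity; an optional list
#' of column-stochastic `g x g` matrices `D` (one per age class) supports
#' dynamic-frailty models, giving `U_tilde = D_blk t(K) U K`.
#'
#' @param params A [ggm_params()] object.
#' @param frailty A [discretize_frailty()] grid.
#' @param omega Number of age classes (default 150).
#' @param D Optional list of `omega` column-stochastic `g x g` frailty
#'   transition matrices; `NULL` (default) means frailty is fixed.
#' @return An object of class `age_frailty_model` holding the sparse
#'   transient matrix `U_tilde`, the dimensions, the model inputs, and the
#'   ordering convention tag.
#' @export
build_projection_matrix <- function(params, frailty, omega = 150, D = NULL) {
  stopifnot(inherits(params, "ggm_params"), inherits(frailty, "frailty_grid"))
  omega <- as.integer(omega)
  g <- frailty$g
  U <- Matrix::bdiag(lapply(frailty$z, survival_matrix, params = params,
                            omega = omega))
  K <- vec_permutation_matrix(g, omega)
  U_tilde <- Matrix::t(K) %*% U %*% K
  if (!is.null(D)) {
    if (!is.list(D) || length(D) != omega) {
      stop("`D` must be a list of ", omega, " g x g matrices", call. = FALSE)
    }
    for (j in seq_along(D)) {
      if (!all(dim(D[[j]]) == c(g, g)) ||
          any(abs(Matrix::colSums(D[[j]]) - 1) > 1e-10) || any(D[[j]] < 0)) {
        stop("D[[", j, "]] is not a column-stochastic g x g matrix",
             call. = FALSE)
      }
    }
    U_tilde <- Matrix::bdiag(D) %*% U_tilde
  }
  structure(
    list(U_tilde = methods::as(U_tilde, "CsparseMatrix"),
         omega = omega, g = g,
         params = params, frailty = frailty,
         ordering = "frailty classes vary fastest within each age block"),
    class = "age_frailty_model"
  )
}

#' @export
print.age_frailty_model <- function(x, ...) {
  cat(sprintf("<age_frailty_model> omega = %d age classes x g = %d frailty classes (%d states)\n",
              x$omega, x$g, x$omega * x$g))
  cat("  ordering:", x$ordering, "\n")
  invisible(x)
}
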