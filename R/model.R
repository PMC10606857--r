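#' Trigonometric design vector for circular covariates
#'
#' Maps `k` angles to the length-`2k + 1` regression basis
#' `(1, cos u_1, sin u_1, ..., cos u_k, sin u_k)`.
#'
#' @param angles numeric vector of `k` angles in radians.
#' @return numeric vector of length `2k + 1`, first entry 1.
#' @examples
#' design_vector(pi / 2)
#' @export
design_vector <- function(angles) {
  if (!is.numeric(angles) || length(angles) == 0L || any(!is.finite(angles))) {
    abort("angles must be a non-empty finite numeric vector",
          class = "robmclr_invalid_input")
  }
  c(1, as.vector(rbind(cos(angles), sin(angles))))
}

# I x (2k+1) design matrix from an I x k angle matrix
design_matrix <- function(U) {
  U <- as.matrix(U)
  k <- ncol(U)
  W <- matrix(1, nrow(U), 2L * k + 1L)
  for (l in seq_len(k)) {
    W[, 2L * l]      <- cos(U[, l])
    W[, 2L * l + 1L] <- sin(U[, l])
  }
  W
}

check_beta <- function(beta, d, k) {
  p <- d * (2L * k + 1L)
  if (!is.numeric(beta) || length(beta) != p || any(!is.finite(beta))) {
    abort(sprintf("`beta` must be a finite numeric vector of length %d (d = %d, k = %d)",
                  p, d, k),
          class = "robmclr_invalid_input")
  }
  invisible(beta)
}

# rows of probabilities from a design matrix; stable softmax with the
# reference (last) category's linear predictor fixed at zero
prob_matrix_design <- function(beta, W, d) {
  B <- matrix(beta, ncol = d)
  Eta <- cbind(W %*% B, 0)
  m <- Eta[cbind(seq_len(nrow(Eta)), max.col(Eta, ties.method = "first"))]
  E <- exp(Eta - m)
  E / rowSums(E)
}

#' Category probabilities of the multinomial circular logistic model
#'
#' For `d + 1` response categories and `k` circular covariates, category
#' `j <= d` has probability `exp(beta_j' w) / (1 + sum_s exp(beta_s' w))`
#' with `w = design_vector(angles)`; the last (reference) category takes
#' the complement. Computed with a max-shifted softmax so large
#' coefficients do not overflow.
#'
#' @param beta parameter vector of length `d * (2k + 1)`, stored as `d`
#'   consecutive per-category blocks
#'   `(intercept, cos u_1, sin u_1, ..., cos u_k, sin u_k)`.
#' @param angles numeric vector of `k` angles (radians), or a matrix
#'   with `k` columns to evaluate several angle tuples at once.
#' @param d number of non-reference categories.
#' @return probability vector of length `d + 1` (or a matrix with
#'   `d + 1` columns), each row summing to one.
#' @examples
#' category_probabilities(rep(0, 6), angles = 1, d = 2)
#' @export
category_probabilities <- function(beta, angles, d) {
  U <- if (is.matrix(angles)) angles else matrix(angles, nrow = 1L)
  if (any(!is.finite(U))) {
    abort("angles must be finite", class = "robmclr_invalid_input")
  }
  check_beta(beta, d, ncol(U))
  P <- prob_matrix_design(beta, design_matrix(U), d)
  if (is.matrix(angles)) P else drop(P)
}

#' Log-likelihood of grouped multinomial circular data
#'
#' Computes `sum_i sum_j nu_ij log pi_ij(beta)` over the covariate
#' patterns (the multinomial-coefficient constant is dropped). Cells
#' with zero count contribute exactly zero even when the fitted
#' probability underflows.
#'
#' @param beta parameter vector.
#' @param data an [mclr_data] object.
#' @return log-likelihood value (a scalar).
#' @export
mclr_loglik <- function(beta, data) {
  md <- unpack_mclr(data)
  check_beta(beta, md$d, md$k)
  P <- prob_matrix_design(beta, design_matrix(md$U), md$d)
  sum(md$V * log(clip_prob(P)))
}

#' Jacobian of category probabilities with respect to the parameters
#'
#' Returns the `p x (d + 1)` matrix whose column `j` is
#' `d pi_j / d beta` at one covariate pattern. Block `s` of column `j`
#' is `pi_j (1\{j = s\} - pi_s) * w`, i.e. the matrix is
#' `t(Delta-tilde(pi)) (x) w` with `Delta(p) = diag(p) - p p'` truncated
#' to its first `d` rows and `w` the design vector.
#'
#' @inheritParams category_probabilities
#' @param angles numeric vector of `k` angles (one pattern).
#' @return matrix with `d * (2k + 1)` rows and `d + 1` columns; columns
#'   sum to zero.
#' @export
probability_jacobian <- function(beta, angles, d) {
  w <- design_vector(angles)
  k <- length(angles)
  check_beta(beta, d, k)
  p <- category_probabilities(beta, angles, d)
  Delta <- diag(p) - tcrossprod(p)
  # rows s = 1..d of Delta give the per-block factors; kron with w
  kronecker(Delta[seq_len(d), , drop = FALSE], matrix(w, ncol = 1L))
}
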