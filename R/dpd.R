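# Density power divergence machinery.
#
# The fitted criterion is the empirical DPD between the joint
# (pattern, category) relative frequencies nu_ij / n and the model cell
# probabilities (n_i / n) * pi_ij(beta):
#
#   H_{n,a}(beta) = n^-(1+a) * sum_ij [ n_i^(1+a) pi_ij^(1+a)
#                   - (1 + 1/a) nu_ij n_i^a pi_ij^a + (1/a) nu_ij^(1+a) ]
#
# As a -> 0 this converges (up to a constant) to the negative mean
# log-likelihood, so the a = 0 estimator is the MLE; that limit is
# implemented as an explicit branch rather than through the 1/a terms.

objective_value <- function(beta, md, alpha) {
  P <- prob_matrix_design(beta, design_matrix(md$U), md$d)
  if (alpha == 0) {
    return(-sum(md$V * log(clip_prob(P))) / md$n)
  }
  ni <- md$ni
  t1 <- sum(ni^(1 + alpha) * rowSums(P^(1 + alpha)))
  t2 <- (1 + 1 / alpha) * sum(ni^alpha * rowSums(md$V * P^alpha))
  t3 <- sum(md$V^(1 + alpha)) / alpha
  (t1 - t2 + t3) / md$n^(1 + alpha)
}

# gradient of objective_value; for alpha > 0 this is
# -(1+a)/n^(1+a) times the estimating-equation sum
#   sum_i n_i^a [Delta-tilde(pi_i) diag^(a-1)(pi_i) (nu_i - n_i pi_i)] (x) w_i,
# and for alpha = 0 it is -(1/n) sum_i (nu_i* - n_i pi_i*) (x) w_i,
# the (negated, scaled) maximum-likelihood score.
gradient_value <- function(beta, md, alpha) {
  W <- design_matrix(md$U)
  P <- prob_matrix_design(beta, W, md$d)
  d <- md$d
  jj <- seq_len(d)
  if (alpha == 0) {
    Bmat <- md$V[, jj, drop = FALSE] - md$ni * P[, jj, drop = FALSE]
    G <- crossprod(W, Bmat)
    return(-as.vector(G) / md$n)
  }
  A <- clip_prob(P)^(alpha - 1) * (md$V - md$ni * P)
  s <- rowSums(P * A)
  Bmat <- P[, jj, drop = FALSE] * (A[, jj, drop = FALSE] - s)
  G <- crossprod(W, md$ni^alpha * Bmat)
  -as.vector(G) * (1 + alpha) / md$n^(1 + alpha)
}

#' Density power divergence objective for grouped circular data
#'
#' Evaluates the empirical DPD criterion `H_{n, alpha}(beta)` whose
#' minimizer is the MDPDE. Requires `alpha > 0`; the `alpha = 0`
#' (maximum likelihood) limit is the negative mean log-likelihood and is
#' handled by [mclr_fit()] directly.
#'
#' @param beta parameter vector of length `d * (2k + 1)`.
#' @param data an [mclr_data] object.
#' @param alpha robustness tuning parameter, strictly positive.
#' @return scalar objective value.
#' @seealso [dpd_gradient()], [mclr_fit()]
#' @export
dpd_objective <- function(beta, data, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive number (use mclr_fit for alpha = 0)",
          class = "robmclr_invalid_parameter")
  }
  md <- unpack_mclr(data)
  check_beta(beta, md$d, md$k)
  objective_value(beta, md, alpha)
}

#' Analytic gradient of the DPD objective
#'
#' Exact gradient of [dpd_objective()] for `alpha > 0`, and of the
#' negative mean log-likelihood for `alpha = 0`. A zero of this vector
#' is exactly a root of the MDPDE estimating equations (the MLE score
#' equations at `alpha = 0`); the gradient equals the estimating-equation
#' sum times `-(1 + alpha) / n^(1 + alpha)`.
#'
#' @inheritParams dpd_objective
#' @param alpha robustness tuning parameter, `>= 0`.
#' @return numeric vector of length `d * (2k + 1)`.
#' @export
dpd_gradient <- function(beta, data, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    abort("`alpha` must be a single non-negative number",
          class = "robmclr_invalid_parameter")
  }
  md <- unpack_mclr(data)
  check_beta(beta, md$d, md$k)
  gradient_value(beta, md, alpha)
}
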