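# Sandwich asymptotics for the MDPDE.
#
# With Delta(p) = diag(p) - p p', Delta-tilde(p) = (I_d | 0) Delta(p),
# D = diag(pi_i) and w_i the design vector:
#
#   Psi_{n,a}   = sum_i (n_i/n)^(1+a)  [Dt D^(a-1) Dt'        ] (x) w_i w_i'
#   Omega_{n,a} = sum_i (n_i/n)^(1+2a) [Dt D^(a-1) Delta D^(a-1) Dt'] (x) w_i w_i'
#
# Psi is 1/n^(1+a) times the expected negative Jacobian of the
# estimating-equation sum; Omega is 1/n^(1+2a) times its exact
# covariance (Var(nu_i) = n_i Delta(pi_i) gives the n_i^(1+2a) weight).
# The estimated covariance of beta-hat is Psi^-1 Omega Psi^-1 / n.
# At alpha = 0 the two matrices coincide (Delta D^-1 Delta = Delta) and
# the sandwich collapses to the inverse Fisher information.

psi_omega_terms <- function(beta, md, alpha, which = c("psi", "omega")) {
  which <- match.arg(which)
  W <- design_matrix(md$U)
  P <- prob_matrix_design(beta, W, md$d)
  d <- md$d
  p <- md$p
  out <- matrix(0, p, p)
  expo <- if (which == "psi") 1 + alpha else 1 + 2 * alpha
  for (i in seq_len(md$I)) {
    pi_i <- P[i, ]
    Delta <- diag(pi_i) - tcrossprod(pi_i)
    Dt <- Delta[seq_len(d), , drop = FALSE]
    da <- clip_prob(pi_i)^(alpha - 1)
    M <- if (which == "psi") {
      Dt %*% (da * t(Dt))
    } else {
      Dt %*% (da * Delta) %*% (da * t(Dt))
    }
    out <- out + (md$ni[i] / md$n)^expo *
      kronecker(M, tcrossprod(W[i, ]))
  }
  (out + t(out)) / 2
}

#' Sensitivity matrix of the MDPDE estimating equations
#'
#' Finite-sample plug-in `Psi_{n, alpha}`: the pattern-weighted sum of
#' `Delta-tilde(pi) diag^(alpha-1)(pi) Delta-tilde(pi)'` Kronecker the
#' design outer product, with weights `(n_i / n)^(1 + alpha)`. At
#' `alpha = 0` it is the Fisher information of the grouped multinomial
#' logit.
#'
#' @inheritParams dpd_gradient
#' @return symmetric `p x p` matrix, `p = d(2k + 1)`.
#' @seealso [omega_matrix()], [sandwich_vcov()]
#' @export
psi_matrix <- function(beta, data, alpha = 0) {
  md <- unpack_mclr(data)
  check_beta(beta, md$d, md$k)
  psi_omega_terms(beta, md, alpha, "psi")
}

#' Variability matrix of the MDPDE estimating equations
#'
#' Finite-sample plug-in `Omega_{n, alpha}`: the covariance of the
#' estimating-equation sum scaled by `n^-(1 + 2 alpha)`, i.e. weights
#' `(n_i / n)^(1 + 2 alpha)` on
#' `Delta-tilde diag^(alpha-1) Delta diag^(alpha-1) Delta-tilde'`
#' Kronecker the design outer product. Coincides with [psi_matrix()]
#' at `alpha = 0`.
#'
#' @inheritParams psi_matrix
#' @return symmetric positive semi-definite `p x p` matrix.
#' @export
omega_matrix <- function(beta, data, alpha = 0) {
  md <- unpack_mclr(data)
  check_beta(beta, md$d, md$k)
  psi_omega_terms(beta, md, alpha, "omega")
}

solve_spd <- function(A, label, cond_max = 1e10) {
  ev <- eigen(A, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) <= 0 || max(lam) / min(lam) > cond_max) {
    worst <- order(lam)[seq_len(min(2L, length(lam)))]
    abort(sprintf(
      "singular information: %s is (near-)singular (condition number > %.0e); deficient directions along eigenvectors %s",
      label, cond_max, paste(worst, collapse = ", ")),
      class = "robmclr_singular_information")
  }
  ev$vectors %*% (t(ev$vectors) / lam)
}

#' Sandwich covariance matrix and standard errors of a fitted model
#'
#' Estimates the covariance of the MDPDE as
#' `Psi^-1 Omega Psi^-1 / n`, both matrices evaluated at the estimate,
#' and attaches standard errors (square roots of the diagonal).
#'
#' @param fit an [mclr_fit] object (converged).
#' @param data the grouped data; defaults to the data stored in `fit`.
#' @return object of class `mclr_sandwich`: a list with elements `psi`,
#'   `omega`, `vcov`, `std_errors` and `alpha`.
#' @export
sandwich_vcov <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  md <- unpack_mclr(data)
  if (!isTRUE(fit$converged)) {
    abort("sandwich covariance requires a converged fit",
          class = "robmclr_invalid_input")
  }
  beta <- fit$beta
  alpha <- fit$alpha
  psi <- psi_omega_terms(beta, md, alpha, "psi")
  omega <- psi_omega_terms(beta, md, alpha, "omega")
  psi_inv <- solve_spd(psi, "Psi_{n,alpha}")
  vc <- psi_inv %*% omega %*% psi_inv / md$n
  vc <- (vc + t(vc)) / 2
  structure(list(psi = psi, omega = omega, vcov = vc,
                 std_errors = sqrt(pmax(diag(vc), 0)), alpha = alpha),
            class = "mclr_sandwich")
}

#' Per-coefficient Wald statistics
#'
#' Computes `z = estimate / std.error` with two-sided p-values from the
#' standard normal reference, using the sandwich standard errors.
#'
#' @param fit a converged [mclr_fit] with standard errors.
#' @return tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
mclr_wald <- function(fit) {
  if (is.null(fit$std_errors)) {
    abort("fit has no standard errors (refit with se = TRUE)",
          class = "robmclr_invalid_input")
  }
  se <- fit$std_errors
  if (any(se == 0)) {
    abort("zero standard error: Wald statistic undefined",
          class = "robmclr_undefined_statistic")
  }
  z <- fit$beta / se
  tibble(term = term_names(fit$d, fit$k, fit$labels),
         estimate = fit$beta, std.error = se,
         statistic = z, p.value = 2 * pnorm(-abs(z)))
}

term_names <- function(d, k, labels = NULL) {
  if (is.null(labels)) labels <- as.character(seq_len(d + 1L))
  base <- c("(Intercept)",
            as.vector(rbind(paste0("cos(u", seq_len(k), ")"),
                            paste0("sin(u", seq_len(k), ")"))))
  as.vector(vapply(labels[seq_len(d)],
                   function(l) paste0(l, ":", base),
                   character(2L * k + 1L)))
}
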