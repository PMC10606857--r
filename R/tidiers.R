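#' Tidy a fitted multinomial circular logistic regression
#'
#' @param x an [mclr_fit] object.
#' @param conf.int include Wald confidence intervals.
#' @param conf.level confidence level.
#' @param ... unused.
#' @return tibble with one row per coefficient: `term`, `estimate` and,
#'   when standard errors are available, `std.error`, `statistic`
#'   (Wald z) and `p.value`.
#' @method tidy mclr_fit
#' @export
tidy.mclr_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  if (is.null(x$std_errors)) {
    out <- tibble(term = term_names(x$d, x$k, x$labels), estimate = x$beta)
  } else {
    out <- mclr_wald(x)
  }
  if (conf.int && !is.null(x$std_errors)) {
    zq <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' One-row summary of a fitted model
#'
#' @param x an [mclr_fit] object.
#' @param ... unused.
#' @return tibble with `alpha`, `objective`, `logLik`, in-sample
#'   `accuracy`, convergence information and problem dimensions.
#' @method glance mclr_fit
#' @export
glance.mclr_fit <- function(x, ...) {
  tibble(alpha = x$alpha,
         objective = x$objective,
         logLik = mclr_loglik(x$beta, x$data),
         accuracy = accuracy(x),
         gradient_norm = x$gradient_norm,
         converged = x$converged,
         iterations = x$iterations,
         n = x$n, n_patterns = x$I,
         df = length(x$beta))
}

#' @rdname tidy.mclr_fit
#' @method tidy mclr_fit_grid
#' @export
tidy.mclr_fit_grid <- function(x, ...) {
  purrr::map_dfr(seq_along(x$alphas), function(i) {
    f <- x$fits[[i]]
    if (!inherits(f, "mclr_fit")) return(tibble())
    dplyr::mutate(tidy(f, ...), alpha = x$alphas[i], .before = 1L)
  })
}

#' @rdname glance.mclr_fit
#' @method glance mclr_fit_grid
#' @export
glance.mclr_fit_grid <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    if (!inherits(f, "mclr_fit")) return(tibble())
    glance(f)
  })
}
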