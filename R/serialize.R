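#' Save and restore a fitted model as JSON
#'
#' The JSON artifact stores the estimate, tuning parameter, model
#' dimensions, category labels and (when present) the sandwich
#' covariance — enough to predict and classify with
#' [predict.mclr_fit()] / [classify()]. The training data are not
#' stored.
#'
#' @param fit an [mclr_fit] object.
#' @param path output/input JSON file.
#' @return `write_mclr_fit()` returns `fit` invisibly;
#'   `read_mclr_fit()` returns an [mclr_fit] object (without data).
#' @export
write_mclr_fit <- function(fit, path) {
  obj <- list(beta = fit$beta, alpha = fit$alpha, d = fit$d, k = fit$k,
              labels = fit$labels, n = fit$n, I = fit$I,
              converged = fit$converged,
              objective = fit$objective,
              vcov = fit$vcov, std_errors = fit$std_errors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(fit)
}

#' @rdname write_mclr_fit
#' @export
read_mclr_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- if (!is.null(obj$vcov)) as.matrix(obj$vcov) else NULL
  structure(list(beta = as.numeric(obj$beta), alpha = obj$alpha,
                 objective = obj$objective, gradient_norm = NA_real_,
                 converged = isTRUE(obj$converged), diverged = FALSE,
                 iterations = NA_integer_,
                 vcov = vc,
                 std_errors = if (!is.null(obj$std_errors)) as.numeric(obj$std_errors) else NULL,
                 d = as.integer(obj$d), k = as.integer(obj$k),
                 labels = as.character(obj$labels),
                 n = obj$n, I = obj$I, message = NULL, data = NULL),
            class = "mclr_fit")
}
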