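#' Predict from a fitted multinomial circular logistic regression
#'
#' @param object an [mclr_fit] object.
#' @param newdata angles at which to predict: a numeric vector (one
#'   angle per observation when `k = 1`), a matrix with `k` columns, or
#'   an [mclr_data] object (its patterns are used). Defaults to the
#'   training patterns.
#' @param type `"class"` for the maximum-probability category label,
#'   `"prob"` for fitted probabilities.
#' @param unit unit of `newdata` angles, `"radians"` (default) or
#'   `"degrees"`.
#' @param ... unused.
#' @return for `type = "prob"`, a tibble of fitted probabilities (one
#'   column per category label); for `type = "class"`, a character
#'   vector of labels. Ties go to the lowest category index.
#' @export
predict.mclr_fit <- function(object, newdata = NULL,
                             type = c("class", "prob"),
                             unit = c("radians", "degrees"), ...) {
  type <- match.arg(type)
  unit <- match.arg(unit)
  U <- resolve_angles(object, newdata, unit)
  P <- category_probabilities(object$beta, U, object$d)
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  colnames(P) <- object$labels
  if (type == "prob") return(as_tibble(P))
  object$labels[max.col(P, ties.method = "first")]
}

resolve_angles <- function(fit, newdata, unit = "radians") {
  if (is.null(newdata)) newdata <- fit$data
  if (inherits(newdata, "mclr_data")) {
    return(unpack_mclr(newdata)$U)
  }
  U <- if (is.matrix(newdata)) newdata else matrix(as.numeric(newdata), ncol = fit$k)
  if (ncol(U) != fit$k) {
    abort(sprintf("`newdata` must supply %d angle(s) per observation", fit$k),
          class = "robmclr_invalid_input")
  }
  if (unit == "degrees") U <- U * pi / 180
  U %% (2 * pi)
}

#' Classify observations by maximum fitted probability
#'
#' Assigns each angle tuple to the category with the largest fitted
#' probability (ties broken toward the lowest category index) and
#' returns the full probability vector alongside.
#'
#' @inheritParams predict.mclr_fit
#' @param fit a converged [mclr_fit].
#' @param angles angles to classify (vector, matrix or [mclr_data]).
#' @return tibble with `.pred_class` and one `.prob_<label>` column per
#'   category.
#' @export
classify <- function(fit, angles, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  U <- resolve_angles(fit, angles, unit)
  P <- category_probabilities(fit$beta, U, fit$d)
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  pred <- fit$labels[max.col(P, ties.method = "first")]
  colnames(P) <- paste0(".prob_", fit$labels)
  dplyr::bind_cols(tibble(.pred_class = pred), as_tibble(P))
}

#' Classification accuracy on grouped data
#'
#' Fraction of observations whose recorded category equals the
#' maximum-probability category predicted at their covariate pattern:
#' `sum_i nu_{i, chat(u_i)} / n`. With `data = NULL` this is the
#' in-sample accuracy on the training data; pass new grouped data for
#' out-of-sample accuracy.
#'
#' @param fit a converged [mclr_fit].
#' @param data an [mclr_data] object (default: training data).
#' @return scalar in `[0, 1]`.
#' @export
accuracy <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  md <- unpack_mclr(data)
  if (md$d != fit$d || md$k != fit$k) {
    abort("`data` dimensions do not match the fitted model",
          class = "robmclr_invalid_input")
  }
  P <- prob_matrix_design(fit$beta, design_matrix(md$U), md$d)
  pred <- max.col(P, ties.method = "first")
  sum(md$V[cbind(seq_len(md$I), pred)]) / md$n
}
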