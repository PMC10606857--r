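#' Plot fitted category-probability curves
#'
#' For a single circular covariate, draws the fitted probability of
#' each category over a fine angle grid, with the observed relative
#' frequencies overlaid as points sized by pattern counts.
#'
#' @param object an [mclr_fit] with `k = 1`.
#' @param n_grid number of grid angles over `[0, 2*pi)`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mclr_fit
#' @export
autoplot.mclr_fit <- function(object, n_grid = 200, ...) {
  if (object$k != 1L) {
    abort("probability-curve plot is only available for k = 1",
          class = "robmclr_invalid_input")
  }
  grid <- seq(0, 2 * pi, length.out = n_grid)
  P <- category_probabilities(object$beta, matrix(grid, ncol = 1), object$d)
  curves <- tibble(angle = rep(grid, object$d + 1L),
                   category = rep(object$labels, each = n_grid),
                   probability = as.vector(P))
  md <- unpack_mclr(object$data)
  obs <- tibble(angle = rep(md$U[, 1L], object$d + 1L),
                category = rep(md$labels, each = md$I),
                probability = as.vector(md$V / md$ni),
                n = rep(md$ni, object$d + 1L))
  ggplot2::ggplot(curves, ggplot2::aes(.data$angle, .data$probability,
                                       colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs, ggplot2::aes(size = .data$n), alpha = 0.4) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "angle (radians)", y = "category probability",
                  title = sprintf("MDPDE fit (alpha = %g)", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot coefficient paths across the tuning-parameter grid
#'
#' @param object an [mclr_fit_grid].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mclr_fit_grid
#' @export
autoplot.mclr_fit_grid <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$alpha, .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "estimate",
                  title = "MDPDE coefficient paths") +
    ggplot2::theme_minimal()
}

#' Plot mean MAE against the tuning parameter for a simulation study
#'
#' @param object an `mclr_study` from [run_simulation_study()].
#' @param ... unused.
#' @return a ggplot object showing the mean (line) and per-replicate
#'   distribution (boxes) of the probability MAE per alpha.
#' @method autoplot mclr_study
#' @export
autoplot.mclr_study <- function(object, ...) {
  sm <- summary(object)
  ggplot2::ggplot(dplyr::filter(object, .data$converged),
                  ggplot2::aes(factor(.data$alpha), .data$mae)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_point(data = sm,
                        ggplot2::aes(factor(.data$alpha), .data$mae_mean),
                        colour = "red", size = 2) +
    ggplot2::labs(x = expression(alpha),
                  y = "MAE of estimated probabilities",
                  title = "Efficiency-robustness trade-off across the alpha grid") +
    ggplot2::theme_minimal()
}
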