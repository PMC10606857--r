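#' Configure a Monte-Carlo contamination study
#'
#' Describes one scenario of the simulation engine: data are generated
#' from the multinomial circular logistic model at `beta_true`,
#' optionally contaminated by forcing a fraction of observations into
#' one category, and refitted along an `alpha` grid; the mean absolute
#' error of the fitted probabilities is recorded per replicate and
#' tuning parameter.
#'
#' Defaults mirror the reference scenario: three categories and one
#' circular covariate with `beta_true = (0, 2, 2, 0.2, 2.5, 1.5)`,
#' pattern sizes drawn uniformly from `1:20`, 10% contamination into
#' category 1, and 500 replications.
#'
#' @param beta_true true parameter vector.
#' @param d number of non-reference categories.
#' @param I number of covariate patterns.
#' @param ni fixed pattern size(s); ignored when `ni_range` is given.
#' @param ni_range integer range from which each `n_i` is drawn
#'   uniformly (default `c(1, 20)`); set to `NULL` to use `ni`.
#' @param law a [circular_law()] for the covariates.
#' @param contamination_rate fraction of observations forced into
#'   `contamination_category` (0 for a clean study).
#' @param contamination_category target category of the outliers.
#' @param alphas ascending grid of tuning parameters.
#' @param replications number of Monte-Carlo replicates.
#' @param seed integer seed; the whole study is reproducible from it.
#' @param resample_angles if `FALSE`, covariate patterns and pattern
#'   sizes are drawn once and reused across replicates (fixed-design
#'   mode).
#' @return list of class `mclr_sim_config`.
#' @export
mclr_sim_config <- function(beta_true = c(0, 2, 2, 0.2, 2.5, 1.5),
                            d = 2, I = 50, ni = 10, ni_range = c(1, 20),
                            law = circular_law("uniform"),
                            contamination_rate = 0.1,
                            contamination_category = 1L,
                            alphas = c(0, 0.2, 0.4, 0.6, 0.8),
                            replications = 500L,
                            seed = 1L,
                            resample_angles = TRUE) {
  stopifnot(replications >= 1, contamination_rate >= 0, contamination_rate < 1)
  structure(list(beta_true = beta_true, d = d, I = I, ni = ni,
                 ni_range = ni_range, law = law,
                 contamination_rate = contamination_rate,
                 contamination_category = as.integer(contamination_category),
                 alphas = alphas, replications = as.integer(replications),
                 seed = as.integer(seed),
                 resample_angles = isTRUE(resample_angles)),
            class = "mclr_sim_config")
}

#' Run a Monte-Carlo contamination study
#'
#' For each replicate: generate clean data, contaminate (if requested),
#' fit the MDPDE along the alpha grid (warm-started along the grid),
#' and record the estimate and the mean absolute error of fitted
#' probabilities against `beta_true` over the replicate's own covariate
#' patterns. Non-converged fits are kept in the table (flagged) but
#' excluded from summaries.
#'
#' @param config an [mclr_sim_config()] object.
#' @param se compute standard errors per fit (off by default; the study
#'   loss does not need them).
#' @param control an [mclr_control()] list.
#' @return tibble of class `mclr_study` with one row per
#'   replicate x alpha: `replicate`, `alpha`, `converged`, `mae`, and
#'   the estimated coefficients `beta_1..beta_p`. The configuration and
#'   non-convergence count are stored as attributes; see
#'   [summary.mclr_study()] and [autoplot.mclr_study()].
#' @examples
#' cfg <- mclr_sim_config(I = 20, replications = 3, alphas = c(0, 0.4), seed = 2)
#' run_simulation_study(cfg)
#' @export
run_simulation_study <- function(config, se = FALSE,
                                 control = mclr_control()) {
  if (!inherits(config, "mclr_sim_config")) {
    abort("`config` must come from mclr_sim_config()",
          class = "robmclr_invalid_input")
  }
  set.seed(config$seed)
  p <- length(config$beta_true)
  fixed <- NULL
  if (!config$resample_angles) {
    fixed <- simulate_mclr_data(config$beta_true, config$d, config$I,
                                ni = config$ni, ni_range = config$ni_range,
                                law = config$law)
  }
  rows <- vector("list", config$replications)
  n_failed_fits <- 0L
  for (r in seq_len(config$replications)) {
    clean <- if (is.null(fixed)) {
      simulate_mclr_data(config$beta_true, config$d, config$I,
                         ni = config$ni, ni_range = config$ni_range,
                         law = config$law)
    } else {
      md <- unpack_mclr(fixed)
      P <- prob_matrix_design(config$beta_true, design_matrix(md$U), md$d)
      V <- t(vapply(seq_len(md$I),
                    function(i) rmultinom(1L, md$ni[i], P[i, ])[, 1L],
                    integer(md$d + 1L)))
      mclr_data(md$U, V, labels = md$labels)
    }
    dat <- if (config$contamination_rate > 0) {
      contaminate(clean, config$contamination_rate,
                  config$contamination_category)
    } else {
      clean
    }
    grid <- mclr_fit_grid(dat, alphas = config$alphas, se = se,
                          control = control)
    rows[[r]] <- purrr::map_dfr(seq_along(grid$alphas), function(i) {
      f <- grid$fits[[i]]
      if (!inherits(f, "mclr_fit")) {
        n_failed_fits <<- n_failed_fits + 1L
        est <- rep(NA_real_, p)
        conv <- FALSE
        mae <- NA_real_
      } else {
        est <- f$beta
        conv <- f$converged
        mae <- mae_probabilities(f$beta, config$beta_true, clean)
        if (!conv) n_failed_fits <<- n_failed_fits + 1L
      }
      out <- tibble(replicate = r, alpha = grid$alphas[i],
                    converged = conv, mae = mae)
      est_tb <- as_tibble(as.list(stats::setNames(est, paste0("beta_", seq_len(p)))))
      dplyr::bind_cols(out, est_tb)
    })
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
            config = config, n_failed_fits = n_failed_fits,
            class = c("mclr_study", class(out)))
}

#' Summarize a simulation study per tuning parameter
#'
#' @param object an `mclr_study` tibble from [run_simulation_study()].
#' @param ... unused.
#' @return tibble with one row per alpha: number of converged
#'   replicates used, mean, median and standard deviation of the MAE.
#' @export
summary.mclr_study <- function(object, ...) {
  out <- object |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(n_used = dplyr::n(),
                     mae_mean = mean(.data$mae),
                     mae_median = median(.data$mae),
                     mae_sd = sd(.data$mae),
                     .groups = "drop")
  attr(out, "n_failed_fits") <- attr(object, "n_failed_fits")
  out
}

#' Write study results to disk
#'
#' Writes the tidy per-replicate table as CSV and the scenario
#' configuration as a JSON sidecar (`<path>.config.json`).
#'
#' @param study an `mclr_study` tibble.
#' @param path CSV output path.
#' @return `study`, invisibly.
#' @export
write_study_results <- function(study, path) {
  readr::write_csv(as.data.frame(study), path)
  cfg <- attr(study, "config")
  cfg$law <- unclass(cfg$law)
  jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(study)
}
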