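#' Circular covariate distributions
#'
#' Describes the law used to draw angular covariates: circular uniform,
#' von Mises (density proportional to `exp(kappa * cos(theta - mu))`),
#' or spherical normal (density proportional to
#' `exp(-(kappa / 2) * delta(theta, mu)^2)` with `delta` the wrapped
#' geodesic distance on the circle).
#'
#' @param family `"uniform"`, `"von_mises"` or `"spherical_normal"`.
#' @param mu mean direction in radians (wrapped to `[0, 2*pi)`).
#' @param kappa concentration, `>= 0`; ignored for the uniform law.
#' @return list of class `circular_law`.
#' @examples
#' circular_law("von_mises", mu = pi / 3, kappa = 2)
#' @export
circular_law <- function(family = c("uniform", "von_mises", "spherical_normal"),
                         mu = 0, kappa = 0) {
  family <- match.arg(family)
  if (!is.finite(kappa) || kappa < 0) {
    abort("`kappa` must be non-negative", class = "robmclr_invalid_parameter")
  }
  structure(list(family = family, mu = mu %% (2 * pi), kappa = kappa),
            class = "circular_law")
}

# Best-Fisher (1979) wrapped-Cauchy rejection sampler for von Mises
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling(1.6 * (n - length(out))) + 8L
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, theta)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

# spherical normal on the circle == mean direction plus a N(0, 1/kappa)
# geodesic offset truncated to [-pi, pi]; sampled exactly by rejection
# of the unconstrained Gaussian draw
rsphnorm <- function(n, mu, kappa) {
  if (kappa <= 0) {
    abort("spherical normal requires kappa > 0",
          class = "robmclr_invalid_parameter")
  }
  sdv <- 1 / sqrt(kappa)
  out <- numeric(0)
  while (length(out) < n) {
    z <- rnorm(ceiling(1.2 * (n - length(out))) + 8L, 0, sdv)
    out <- c(out, z[abs(z) <= pi])
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Draw angles from a circular law
#'
#' Uses R's global random number stream (`set.seed()` for
#' reproducibility).
#'
#' @param n number of draws, `>= 0`.
#' @param law a [circular_law()] object.
#' @return numeric vector of `n` angles in `[0, 2*pi)`.
#' @examples
#' set.seed(1)
#' sample_circular(5, circular_law("von_mises", mu = pi / 3, kappa = 2))
#' @export
sample_circular <- function(n, law) {
  if (!inherits(law, "circular_law")) {
    abort("`law` must be a circular_law()", class = "robmclr_invalid_input")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer",
          class = "robmclr_invalid_input")
  }
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  switch(law$family,
         uniform = runif(n, 0, 2 * pi),
         von_mises = rvonmises(n, law$mu, law$kappa),
         spherical_normal = rsphnorm(n, law$mu, law$kappa))
}

#' Simulate grouped data from the multinomial circular logistic model
#'
#' Draws `I` covariate patterns (angles i.i.d. from `law`, one law for
#' every circular covariate), pattern sizes `n_i`, and category counts
#' `nu_i ~ Multinomial(n_i, pi_i(beta))`.
#'
#' @param beta true parameter vector of length `d * (2k + 1)`.
#' @param d number of non-reference categories.
#' @param I number of covariate patterns.
#' @param ni pattern sizes: a single integer (recycled) or a vector of
#'   length `I`. Ignored when `ni_range` is given.
#' @param ni_range optional integer range `c(lo, hi)`; each `n_i` is
#'   drawn uniformly from `lo:hi`.
#' @param law a [circular_law()] for the covariates.
#' @param labels optional category labels.
#' @return an [mclr_data] tibble.
#' @examples
#' set.seed(7)
#' simulate_mclr_data(c(0, 2, 2, 0.2, 2.5, 1.5), d = 2, I = 5, ni_range = c(1, 20))
#' @export
simulate_mclr_data <- function(beta, d, I, ni = 10, ni_range = NULL,
                               law = circular_law("uniform"),
                               labels = NULL) {
  if (length(beta) %% d != 0 || (length(beta) / d - 1) %% 2 != 0) {
    abort("`beta` length must be d * (2k + 1)", class = "robmclr_invalid_input")
  }
  k <- as.integer((length(beta) / d - 1) / 2)
  check_beta(beta, d, k)
  U <- matrix(sample_circular(I * k, law), I, k)
  sizes <- if (!is.null(ni_range)) {
    sample(seq.int(ni_range[1], ni_range[2]), I, replace = TRUE)
  } else {
    rep_len(as.integer(ni), I)
  }
  P <- prob_matrix_design(beta, design_matrix(U), d)
  V <- t(vapply(seq_len(I),
                function(i) rmultinom(1L, sizes[i], P[i, ])[, 1L],
                integer(d + 1L)))
  mclr_data(U, V, labels = labels)
}

#' Contaminate grouped data by forced misclassification
#'
#' Selects `round(rate * n)` individual observations uniformly at
#' random without replacement across all patterns (probability
#' proportional to cell counts) and reassigns each to
#' `target_category`, regardless of its covariate value. Angles, the
#' number of patterns and the total sample size are unchanged; only the
#' counts move.
#'
#' @param data an [mclr_data] object.
#' @param rate contamination fraction in `[0, 1)`.
#' @param target_category index of the category outliers are forced
#'   into (default 1).
#' @return contaminated [mclr_data] tibble.
#' @export
contaminate <- function(data, rate, target_category = 1L) {
  md <- unpack_mclr(data)
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort("`rate` must be in [0, 1)", class = "robmclr_invalid_parameter")
  }
  m <- round(rate * md$n)
  if (m == 0) return(data)
  # one entry per observation: its (pattern, category) cell
  cell_pat <- rep(rep(seq_len(md$I), times = md$d + 1L), times = as.vector(md$V))
  cell_cat <- rep(rep(seq_len(md$d + 1L), each = md$I), times = as.vector(md$V))
  pick <- sample.int(md$n, m)
  V <- md$V
  for (r in pick) {
    j <- cell_cat[r]
    if (j == target_category) next
    i <- cell_pat[r]
    V[i, j] <- V[i, j] - 1L
    V[i, target_category] <- V[i, target_category] + 1L
  }
  mclr_data(md$U, V, labels = md$labels)
}

#' Mean absolute error of fitted category probabilities
#'
#' Averages `|pi_ij(beta_hat) - pi_ij(beta_true)|` over the `I`
#' covariate patterns and all `d + 1` categories — the loss used to
#' compare estimators in contamination studies.
#'
#' @param beta_hat,beta_true parameter vectors for the same model
#'   dimensions.
#' @param data an [mclr_data] object supplying the covariate patterns
#'   (its counts are not used).
#' @return scalar in `[0, 2d / (d + 1)]`.
#' @export
mae_probabilities <- function(beta_hat, beta_true, data) {
  md <- unpack_mclr(data)
  if (md$I == 0L) abort("empty pattern list", class = "robmclr_invalid_input")
  check_beta(beta_hat, md$d, md$k)
  check_beta(beta_true, md$d, md$k)
  W <- design_matrix(md$U)
  mean(abs(prob_matrix_design(beta_hat, W, md$d) -
             prob_matrix_design(beta_true, W, md$d)))
}
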