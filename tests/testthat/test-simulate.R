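test_that("uniform sampler has vanishing resultant length", {
  set.seed(201)
  th <- sample_circular(1e5, circular_law("uniform"))
  expect_true(all(th >= 0 & th < 2 * pi))
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(rbar, 0.02)
})

test_that("von Mises sampler matches the Bessel-ratio resultant length", {
  set.seed(202)
  for (kappa in c(2, 6)) {
    th <- sample_circular(1e5, circular_law("von_mises", mu = pi / 3, kappa = kappa))
    C <- mean(cos(th)); S <- mean(sin(th))
    rbar <- sqrt(C^2 + S^2)
    mu_hat <- atan2(S, C) %% (2 * pi)
    expect_lt(abs(rbar - besselI(kappa, 1) / besselI(kappa, 0)), 0.02)
    expect_lt(abs(mu_hat - pi / 3), 0.02)
  }
})

test_that("spherical normal sampler matches its quadrature-normalized density", {
  set.seed(203)
  mu <- pi / 3; kappa <- 6
  th <- sample_circular(1e5, circular_law("spherical_normal", mu = mu, kappa = kappa))
  breaks <- seq(0, 2 * pi, length.out = 51)
  h <- hist(th, breaks = breaks, plot = FALSE)
  centers <- h$mids
  geo <- function(x) ((x - mu + pi) %% (2 * pi)) - pi
  dens <- exp(-kappa / 2 * geo(centers)^2)
  norm_const <- stats::integrate(function(x) exp(-kappa / 2 * geo(x)^2),
                                 0, 2 * pi, subdivisions = 500L)$value
  expect_lt(max(abs(h$density - dens / norm_const)), 0.05)
})

test_that("generated counts follow the model probabilities", {
  set.seed(204)
  # at beta = 0 pooled category frequencies are uniform
  dat <- simulate_mclr_data(rep(0, 6), d = 2, I = 60, ni = 50)
  md <- robmclr:::unpack_mclr(dat)
  freq <- colSums(md$V)
  expect_true(all(abs(freq - md$n / 3) <= 2 * sqrt(md$n * (1 / 3) * (2 / 3))))
  # a large pattern reproduces its own cell probabilities
  dat2 <- simulate_mclr_data(beta_ref, d = 2, I = 3, ni = 1e4)
  md2 <- robmclr:::unpack_mclr(dat2)
  P <- robmclr:::prob_matrix_design(beta_ref, robmclr:::design_matrix(md2$U), 2)
  for (i in 1:3) {
    sdbin <- sqrt(P[i, ] * (1 - P[i, ]) / 1e4)
    expect_true(all(abs(md2$V[i, ] / 1e4 - P[i, ]) <= 3 * sdbin + 1e-4))
  }
})

test_that("generation is reproducible from the seed", {
  set.seed(42)
  d1 <- simulate_mclr_data(beta_ref, d = 2, I = 20, ni_range = c(1, 20))
  set.seed(42)
  d2 <- simulate_mclr_data(beta_ref, d = 2, I = 20, ni_range = c(1, 20))
  expect_identical(d1, d2)
})

test_that("contamination moves exactly the requested number of observations", {
  set.seed(205)
  dat <- simulate_mclr_data(beta_ref, d = 2, I = 25, ni = 20) # n = 500
  md <- robmclr:::unpack_mclr(dat)
  expect_identical(contaminate(dat, 0), dat)
  out <- contaminate(dat, 0.1, 1L)
  mo <- robmclr:::unpack_mclr(out)
  expect_equal(mo$ni, md$ni)          # pattern totals conserved
  expect_equal(mo$U, md$U)            # angles untouched
  moved_into_1 <- sum(mo$V[, 1]) - sum(md$V[, 1])
  removed <- sum(pmax(md$V[, -1] - mo$V[, -1], 0))
  expect_equal(moved_into_1, removed)
  expect_lte(moved_into_1, 50)        # 50 draws, some already in category 1
  expect_gt(moved_into_1, 0)
  expect_error(contaminate(dat, 1), class = "robmclr_invalid_parameter")
})

test_that("per-pattern displacement follows the hypergeometric allocation", {
  set.seed(206)
  # 2 patterns, all mass outside category 1; picking m of n observations
  # without replacement removes Hypergeometric(n, n_i, m) from pattern i
  dat <- mclr_data(c(0.5, 2.0), rbind(c(0L, 30L, 10L), c(0L, 10L, 10L)))
  m <- 6 # rate 0.1 of n = 60
  reps <- 1000
  taken1 <- numeric(reps)
  for (r in seq_len(reps)) {
    out <- robmclr:::unpack_mclr(contaminate(dat, 0.1, 1L))
    taken1[r] <- out$V[1, 1]
  }
  expect_equal(mean(taken1), m * 40 / 60, tolerance = 0.05)
  expect_equal(stats::var(taken1),
               m * (40 / 60) * (20 / 60) * (60 - m) / 59,
               tolerance = 0.15)
})

test_that("probability MAE behaves as a distance on the simplex", {
  dat <- simulate_mclr_data(beta_ref, d = 2, I = 10, ni = 5)
  expect_equal(mae_probabilities(beta_ref, beta_ref, dat), 0)
  # binary single pattern: (0.6, 0.4) vs (0.5, 0.5) -> 0.1
  dat1 <- mclr_data(0, matrix(c(1L, 1L), 1))
  b_half <- c(0, 0, 0)
  b_06 <- c(log(0.6 / 0.4), 0, 0)
  expect_equal(mae_probabilities(b_06, b_half, dat1), 0.1, tolerance = 1e-12)
  # bounded by 2d/(d+1)
  set.seed(207)
  for (r in 1:50) {
    b1 <- rnorm(6, sd = 8); b2 <- rnorm(6, sd = 8)
    expect_lte(mae_probabilities(b1, b2, dat), 2 * 2 / 3)
  }
})

test_that("simulation studies are reproducible and tidily summarized", {
  cfg <- mclr_sim_config(I = 15, ni_range = c(5, 15), replications = 4,
                         alphas = c(0, 0.4), seed = 7,
                         contamination_rate = 0.1)
  s1 <- run_simulation_study(cfg)
  s2 <- run_simulation_study(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(nrow(s1), 8)
  expect_true(all(c("replicate", "alpha", "converged", "mae", "beta_1") %in%
                    names(s1)))
  expect_true(all(s1$mae[s1$converged] >= 0 & s1$mae[s1$converged] <= 1))
  sm <- summary(s1)
  expect_true(all(c("alpha", "n_used", "mae_mean", "mae_median", "mae_sd") %in%
                    names(sm)))
  expect_lte(nrow(sm), 2)
})

test_that("fixed-design mode reuses the covariate patterns across replicates", {
  cfg <- mclr_sim_config(I = 10, ni = 8, ni_range = NULL, replications = 3,
                         alphas = 0, seed = 11, contamination_rate = 0,
                         resample_angles = FALSE)
  st <- run_simulation_study(cfg)
  expect_equal(nrow(st), 3)
  expect_true(all(st$converged | is.na(st$mae)))
})

test_that("study results round-trip through the CSV writer", {
  cfg <- mclr_sim_config(I = 12, ni = 10, ni_range = NULL, replications = 2,
                         alphas = c(0, 0.4), seed = 5)
  st <- run_simulation_study(cfg)
  tmp <- tempfile(fileext = ".csv")
  write_study_results(st, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(st))
  expect_equal(back$mae, st$mae)
  cfg_back <- jsonlite::read_json(paste0(tmp, ".config.json"),
                                  simplifyVector = TRUE)
  expect_equal(cfg_back$seed, 5)
  unlink(c(tmp, paste0(tmp, ".config.json")))
})

test_that("MAE shrinks as the number of patterns grows, for every covariate law", {
  mae_for <- function(I, law, rate, seed, alphas = 0) {
    st <- run_simulation_study(mclr_sim_config(
      I = I, ni = 10, ni_range = NULL, law = law,
      contamination_rate = rate, alphas = alphas,
      replications = 30, seed = seed))
    summary(st)$mae_mean[1]
  }
  unif <- circular_law("uniform")
  expect_lt(mae_for(100, unif, 0, 401), mae_for(20, unif, 0, 402))
  expect_lt(mae_for(100, unif, 0.1, 403), mae_for(20, unif, 0.1, 404))
  # von Mises and spherical normal scenario designs run end-to-end
  vm <- circular_law("von_mises", mu = pi / 3, kappa = 2)
  sn <- circular_law("spherical_normal", mu = pi / 3, kappa = 6)
  for (law in list(vm, sn)) {
    st <- run_simulation_study(mclr_sim_config(
      I = 50, ni = 5, ni_range = NULL, law = law,
      contamination_rate = 0.1, alphas = c(0, 0.4),
      replications = 10, seed = 405))
    sm <- summary(st)
    expect_true(all(sm$n_used >= 8))
    expect_true(all(sm$mae_mean < 0.2))
  }
})
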