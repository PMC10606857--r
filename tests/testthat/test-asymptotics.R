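test_that("psi and omega coincide at alpha = 0 and match the Fisher information", {
  set.seed(71)
  for (r in 1:50) {
    dat <- random_data(I = sample(4:10, 1), d = sample(1:3, 1), k = 1)
    b <- rnorm(robmclr:::unpack_mclr(dat)$p)
    psi0 <- psi_matrix(b, dat, 0)
    om0 <- omega_matrix(b, dat, 0)
    expect_lt(max(abs(psi0 - om0)), 1e-12)
  }
  # alpha = 0 psi equals the independently assembled information
  # sum_i (n_i / n) Delta(pi_i*) (x) w_i w_i'
  set.seed(72)
  dat <- random_data(I = 6, d = 2, k = 1)
  md <- robmclr:::unpack_mclr(dat)
  b <- rnorm(6)
  info <- matrix(0, 6, 6)
  for (i in seq_len(md$I)) {
    w <- c(1, cos(md$U[i, 1]), sin(md$U[i, 1]))
    ps <- oracle_probs(b, md$U[i, ], 2)[1:2]
    info <- info + (md$ni[i] / md$n) *
      kronecker(diag(ps) - ps %o% ps, w %o% w)
  }
  expect_equal(psi_matrix(b, dat, 0), info, tolerance = 1e-10)
})

test_that("single-pattern binary psi matches the scalar closed form", {
  # d = 1, k = 1, one pattern: psi = (n1/n)^(1+a) pi^(a-1) (1-pi) *
  #   [pi (1 - pi) + pi^2 ... ] reduces to Delta D^(a-1) Delta on a
  #   2-simplex: m = pi1 pi2 (pi1^a pi2 + pi2^a pi1) ... worked out
  #   directly below from 2x2 matrices
  b <- c(0.3, -0.8, 0.5); u <- 1.2; alpha <- 0.4
  dat <- mclr_data(u, matrix(c(6L, 4L), 1))
  p <- oracle_probs(b, u, 1)
  w <- c(1, cos(u), sin(u))
  Delta <- diag(p) - p %o% p
  Dt <- Delta[1, , drop = FALSE]
  m_psi <- Dt %*% diag(p^(alpha - 1)) %*% t(Dt)
  # scalar simplification: Dt = pi1 pi2 (1, -1), so
  # m = (pi1 pi2)^2 (pi1^(a-1) + pi2^(a-1))
  expect_equal(as.numeric(m_psi),
               (p[1] * p[2])^2 * (p[1]^(alpha - 1) + p[2]^(alpha - 1)))
  expect_equal(psi_matrix(b, dat, alpha),
               as.numeric(m_psi) * (w %o% w), # n1 = n so weight 1
               tolerance = 1e-12)
})

test_that("doubling all pattern sizes leaves psi unchanged at alpha = 0", {
  set.seed(81)
  dat <- random_data(I = 5, d = 2, k = 1)
  md <- robmclr:::unpack_mclr(dat)
  dat2 <- mclr_data(md$U, 2L * md$V)
  b <- rnorm(6)
  expect_equal(psi_matrix(b, dat, 0), psi_matrix(b, dat2, 0),
               tolerance = 1e-12)
})

test_that("omega matches the Monte-Carlo covariance of the score sum", {
  set.seed(99)
  d <- 2; I <- 6; alpha <- 0.4
  dat <- simulate_mclr_data(beta_ref, d = d, I = I, ni_range = c(5, 20))
  md <- robmclr:::unpack_mclr(dat)
  P <- robmclr:::prob_matrix_design(beta_ref, robmclr:::design_matrix(md$U), d)
  score_sum <- function(V) {
    s <- rep(0, 6)
    for (i in seq_len(I)) {
      p <- P[i, ]
      Delta <- diag(p) - p %o% p
      a <- p^(alpha - 1) * (V[i, ] - md$ni[i] * p)
      s <- s + md$ni[i]^alpha *
        kronecker((Delta %*% a)[1:2], c(1, cos(md$U[i, 1]), sin(md$U[i, 1])))
    }
    s
  }
  R <- 10000
  S <- t(vapply(seq_len(R), function(r) {
    V <- t(vapply(seq_len(I),
                  function(i) rmultinom(1, md$ni[i], P[i, ])[, 1],
                  integer(d + 1)))
    score_sum(V)
  }, numeric(6)))
  emp <- stats::cov(S)
  om <- omega_matrix(beta_ref, dat, alpha) * md$n^(1 + 2 * alpha)
  expect_lt(norm(emp - om, "F") / norm(om, "F"), 0.05)
})

test_that("omega stays finite under extreme coefficients via the probability floor", {
  dat <- toy_data()
  b <- c(80, 90, -70, -60, 85, 40)
  om <- omega_matrix(b, dat, 0.2)
  expect_true(all(is.finite(om)))
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("sandwich covariance scales as 1/n and collapses to the inverse information", {
  set.seed(111)
  dat <- simulate_mclr_data(beta_ref, d = 2, I = 40, ni = 10)
  f <- mclr_fit(dat, alpha = 0)
  sw <- sandwich_vcov(f)
  expect_equal(sw$vcov, t(sw$vcov))
  ev <- eigen(sw$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # alpha = 0: sandwich is the inverse information over n
  md <- robmclr:::unpack_mclr(dat)
  expect_equal(sw$vcov, solve(sw$psi) / md$n, tolerance = 1e-8)
  # duplicating the data halves the covariance
  md <- robmclr:::unpack_mclr(dat)
  dat2 <- mclr_data(rbind(md$U, md$U), rbind(md$V, md$V))
  f2 <- f; f2$beta <- f$beta
  sw2 <- sandwich_vcov(f2, dat2)
  expect_equal(sw2$vcov, sw$vcov / 2, tolerance = 1e-10)
})

test_that("rank-deficient designs raise a singular-information error", {
  # one covariate pattern cannot identify 6 parameters
  dat <- mclr_data(1.0, matrix(c(4L, 3L, 3L), 1))
  f <- structure(list(beta = rep(0, 6), alpha = 0, converged = TRUE,
                      d = 2, k = 1, labels = as.character(1:3), data = dat),
                 class = "mclr_fit")
  expect_error(sandwich_vcov(f, dat),
               class = "robmclr_singular_information")
})

test_that("Wald statistics follow the routine construction", {
  se <- c(0.5, 1, 2)
  f <- structure(list(beta = c(0, 1.96, -1), std_errors = se,
                      d = 1, k = 1, labels = c("A", "B"),
                      alpha = 0),
                 class = "mclr_fit")
  f$labels <- c("A", "B") # d = 1 -> 3 terms
  w <- mclr_wald(f)
  expect_equal(w$statistic, c(0, 1.96, -0.5))
  expect_equal(w$p.value[1], 1)
  expect_equal(w$p.value[2], 0.05, tolerance = 1e-3)
  f$std_errors <- c(0, 1, 1)
  expect_error(mclr_wald(f), class = "robmclr_undefined_statistic")
})

test_that("null coefficients reject near the nominal 5% level", {
  set.seed(123)
  # intercept of category 1 is zero under the truth; test its Wald test
  b0 <- c(0, 2, 2, 0.2, 2.5, 1.5)
  R <- 500
  rej <- logical(R)
  for (r in seq_len(R)) {
    dat <- simulate_mclr_data(b0, d = 2, I = 50, ni = 10)
    f <- mclr_fit(dat, alpha = 0)
    rej[r] <- !is.null(f$std_errors) && abs(f$beta[1] / f$std_errors[1]) > 1.96
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})
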