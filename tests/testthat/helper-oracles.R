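# Independent oracles used across the test suite. These deliberately
# avoid the package's vectorized/stabilized code paths: probabilities
# are formed by the raw exponential formula, sums by explicit loops.

# raw (unstabilized) model probabilities for one pattern
oracle_probs <- function(beta, u, d) {
  k <- length(u)
  w <- c(1, as.vector(rbind(cos(u), sin(u))))
  eta <- numeric(d)
  for (j in seq_len(d)) {
    bj <- beta[((j - 1) * (2 * k + 1) + 1):(j * (2 * k + 1))]
    eta[j] <- sum(bj * w)
  }
  e <- exp(eta)
  c(e, 1) / (1 + sum(e))
}

# brute-force triple-loop DPD objective
oracle_dpd <- function(beta, data, alpha) {
  md <- robmclr:::unpack_mclr(data)
  total <- 0
  for (i in seq_len(md$I)) {
    p <- oracle_probs(beta, md$U[i, ], md$d)
    for (j in seq_len(md$d + 1)) {
      total <- total +
        md$ni[i]^(1 + alpha) * p[j]^(1 + alpha) -
        (1 + 1 / alpha) * md$V[i, j] * md$ni[i]^alpha * p[j]^alpha +
        md$V[i, j]^(1 + alpha) / alpha
    }
  }
  total / md$n^(1 + alpha)
}

# brute-force log-likelihood double loop
oracle_loglik <- function(beta, data) {
  md <- robmclr:::unpack_mclr(data)
  total <- 0
  for (i in seq_len(md$I)) {
    p <- oracle_probs(beta, md$U[i, ], md$d)
    for (j in seq_len(md$d + 1)) {
      if (md$V[i, j] > 0) total <- total + md$V[i, j] * log(p[j])
    }
  }
  total
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- replace(rep(0, length(x)), j, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Newton-Raphson maximum likelihood solver of the score equations
# sum_i (nu_i* - n_i pi_i*) (x) w_i = 0, written independently of the
# package's optimizer (truncated d x d information, raw probabilities)
oracle_nr_mle <- function(data, tol = 1e-12, maxit = 200) {
  md <- robmclr:::unpack_mclr(data)
  d <- md$d
  p <- md$p
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    score <- rep(0, p)
    info <- matrix(0, p, p)
    for (i in seq_len(md$I)) {
      w <- c(1, as.vector(rbind(cos(md$U[i, ]), sin(md$U[i, ]))))
      pi_i <- oracle_probs(beta, md$U[i, ], d)
      ps <- pi_i[seq_len(d)]
      score <- score + kronecker(md$V[i, seq_len(d)] - md$ni[i] * ps, w)
      info <- info + md$ni[i] *
        kronecker(diag(ps, nrow = d) - ps %o% ps, w %o% w)
    }
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, score = score, iterations = it)
}

# quick grouped dataset builders
toy_data <- function() {
  mclr_data(angles = c(0.3, 1.7, 4.4),
            counts = rbind(c(3, 1, 2), c(0, 4, 1), c(2, 2, 2)))
}

random_data <- function(I = 8, d = 2, k = 1, ni_max = 12) {
  U <- matrix(runif(I * k, 0, 2 * pi), I, k)
  V <- t(sapply(seq_len(I), function(i) {
    n_i <- sample(1:ni_max, 1)
    as.vector(rmultinom(1, n_i, rep(1 / (d + 1), d + 1)))
  }))
  mclr_data(U, V)
}

beta_ref <- c(0, 2, 2, 0.2, 2.5, 1.5)
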