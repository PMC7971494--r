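# Independent oracles used across the suite.

# Closed-form mean of a normal(mean, sd^2) truncated to (lb, ub).
tnorm_mean <- function(mean, sd, lb, ub) {
  a <- (lb - mean) / sd
  b <- (ub - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Coordinate-descent graphical lasso (Friedman-style, penalized diagonal):
# maximizes log det(Omega) - tr(S Omega) - rho ||Omega||_1 over SPD Omega.
# Written independently of the package's proximal-gradient solver.
glasso_cd <- function(S, rho, max_iter = 2000, tol = 1e-12) {
  p <- ncol(S)
  W <- S + rho * diag(p)
  beta <- matrix(0, p - 1, p)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      b <- beta[, j]
      for (cd in 1:500) {
        b_old <- b
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, -k] * b[-k])
          b[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(b - b_old)) < tol) break
      }
      beta[, j] <- b
      W[-j, j] <- W[j, -j] <- W11 %*% b
    }
    if (max(abs(W - W_old)) < tol) break
  }
  Om <- matrix(0, p, p)
  for (j in seq_len(p)) {
    o22 <- 1 / (W[j, j] - sum(W[-j, j] * beta[, j]))
    Om[j, j] <- o22
    Om[-j, j] <- -beta[, j] * o22
  }
  (Om + t(Om)) / 2
}

# Random SPD matrix with unit-scale eigenvalues.
random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + 0.1 * diag(p)
}

# Small mixed-type multilevel dataset for sampler tests.
make_mixed_toy <- function(n_per = 15, m = 4, p = 3, miss = 0,
                           types = c("continuous", "ordinal", "binary")) {
  sim <- simulate_latent(m, n_per, diag(p), 0.3 * diag(p))
  th <- list(NULL, c(0.3, 0.6), 0.5)[seq_len(p)]
  dat <- discretize_latent(sim$Z, sim$cluster, types[seq_len(p)], th)
  if (miss > 0) dat <- inject_missing(dat, miss, "MCAR")
  dat
}

# Does a latent column satisfy the rank event for its observed column?
rank_event_holds <- function(y, z) {
  obs <- !is.na(y)
  y <- y[obs]; z <- z[obs]
  o <- order(y, z)
  all(diff(y[o]) == 0 | diff(z[o]) > 0)
}
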