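test_that("random-effect draws center on the precision-weighted mean", {
  set.seed(51)
  # Psi = I, Omega = I, one row with z = (2, 0): posterior mean z/2
  Z <- matrix(c(2, 0), 1, 2)
  draws <- t(replicate(4000, sample_random_effects(Z, 1L, diag(2), diag(2))[1, ]))
  expect_lt(max(abs(colMeans(draws) - c(1, 0))), 0.05)

  # diffuse Psi: posterior mean approaches the cluster mean of z
  Zc <- matrix(rnorm(40, mean = 3), 20, 2)
  draws <- t(replicate(2000,
    sample_random_effects(Zc, rep(1L, 20), diag(2), 1e6 * diag(2))[1, ]))
  expect_lt(max(abs(colMeans(draws) - colMeans(Zc))), 0.12)

  expect_error(sample_random_effects(Zc, rep(1L, 20), diag(2), diag(2), m = 2),
               "at least one row")
})

test_that("random-effect covariance draws follow the inverse-Wishart", {
  set.seed(52)
  p <- 3; nu <- p + 2; Lambda <- diag(p)
  # m = 0: prior draw
  prior_draw <- sample_psi(matrix(0, 0, p), nu, Lambda)
  expect_true(is_spd(prior_draw))

  B <- matrix(rnorm(10 * p), 10, p)
  scale <- Lambda + crossprod(B)
  draws <- replicate(8000, sample_psi(B, nu, Lambda))
  post_mean <- apply(draws, c(1, 2), mean)
  exact <- scale / (nu + 10 - p - 1)
  expect_lt(max(abs(post_mean - exact) / max(abs(exact))), 0.05)
  expect_true(all(apply(draws[, , 1:50], 3, is_spd)))
})

test_that("shrinkage draws follow Gamma(1 + s, |omega| + t) off-diagonal", {
  set.seed(53)
  s <- 0.01; t <- 1e-4
  om <- matrix(c(1, 0, 0, 1), 2, 2)
  lam <- replicate(2e4, sample_shrinkage(om, s, t)[1, 2])
  # conditional mean at omega = 0 is (1 + s) / t
  expect_lt(abs(mean(lam) / ((1 + s) / t) - 1), 0.05)

  om[1, 2] <- om[2, 1] <- 0.5
  lam <- replicate(1e5, sample_shrinkage(om, s, t)[1, 2])
  mu <- (1 + s) / (0.5 + t)
  se <- sqrt((1 + s)) / (0.5 + t) / sqrt(1e5)
  expect_lt(abs(mean(lam) - mu), 3 * se)
  ks <- suppressWarnings(
    ks.test(lam[1:1e4], "pgamma", shape = 1 + s, rate = 0.5 + t))
  expect_gt(ks$p.value, 0.01)

  # diagonal shrinkage is the fixed constant
  expect_equal(diag(sample_shrinkage(om, s, t, lambda_diag = 2)), c(2, 2))
})

test_that("scale-mixture draws have inverse-Gaussian reciprocals", {
  set.seed(54)
  om <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  lam <- matrix(c(1, 2, 2, 1), 2, 2)
  tau <- replicate(1e5, sample_scaling(om, lam)[1, 2])
  expect_true(all(tau > 0))
  expect_equal(sample_scaling(om, lam)[1, 1], 0)
  # E[1/tau] = lambda / |omega|; Var[1/tau] = mean^3 / shape
  mu <- 2 / 0.4
  se <- sqrt(mu^3 / 2^2) / sqrt(1e5)
  expect_lt(abs(mean(1 / tau) - mu), 3 * se)

  # omega = 0 is floored, draws stay finite
  om0 <- diag(2)
  tau0 <- sample_scaling(om0, lam)
  expect_true(all(is.finite(tau0)))
})

test_that("inverse-Gaussian sampler matches its first two moments", {
  set.seed(55)
  x <- rinvgauss(2e5, mean = 1.5, shape = 3)
  expect_lt(abs(mean(x) - 1.5), 3 * sqrt(1.5^3 / 3 / 2e5))
  expect_lt(abs(var(x) - 1.5^3 / 3) / (1.5^3 / 3), 0.05)
})

test_that("column-wise precision update keeps the matrix SPD", {
  set.seed(56)
  # prior-only conditional: S = 0, N = 0
  p <- 3
  om <- diag(p)
  lam <- matrix(1, p, p)
  tau <- matrix(0.5, p, p); diag(tau) <- 0
  g <- replicate(5000, {
    o <- update_precision_column(om, matrix(0, p, p), tau, lam, 2, 0)
    pp <- partition_column(o, 2)
    pp$m22 - drop(crossprod(pp$m12, solve(pp$M11, pp$m12)))
  })
  # gamma ~ Gamma(1, lambda22 / 2): mean 2 / lambda22
  expect_lt(abs(mean(g) - 2), 3 * 2 / sqrt(5000))

  for (rep in 1:1000) {
    p <- sample(2:6, 1)
    om <- random_spd(p)
    S <- crossprod(matrix(rnorm(20 * p), 20, p))
    lam <- matrix(rgamma(p * p, 2, 1) + 0.1, p, p); lam <- (lam + t(lam)) / 2
    tau <- matrix(rgamma(p * p, 2, 2) + 0.05, p, p)
    tau <- (tau + t(tau)) / 2; diag(tau) <- 0
    om2 <- update_precision_column(om, S, tau, lam, sample(p, 1), 20)
    ev <- eigen(om2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("the precision-column kernel targets the Laplace-prior conditional", {
  # 2 x 2 instance with omega_11 fixed: iterate (scale, column) updates and
  # compare the stationary omega_12 moments against an independent Metropolis
  # sampler for the marginalized conditional density
  # q(b) propto exp(-(s22 + l22) b^2 / (2 w11) - s12 b - l12 |b|).
  set.seed(57)
  w11 <- 2; s22 <- 8; s12 <- -3; l12 <- 2.5; l22 <- 1.5; N <- 10
  om <- matrix(c(w11, 0.1, 0.1, 1), 2, 2)
  S <- matrix(c(5, s12, s12, s22), 2, 2)
  lam <- matrix(c(1, l12, l12, l22), 2, 2)
  ng <- 30000
  og <- numeric(ng)
  for (i in seq_len(ng)) {
    tau <- sample_scaling(om, lam)
    om <- update_precision_column(om, S, tau, lam, 2, N)
    og[i] <- om[1, 2]
  }
  lq <- function(b) -(s22 + l22) * b^2 / (2 * w11) - s12 * b - l12 * abs(b)
  x <- 0; om2 <- numeric(ng)
  for (i in seq_len(ng)) {
    prop <- rnorm(1, 0.75, 0.6)
    lacc <- lq(prop) - lq(x) +
      dnorm(x, 0.75, 0.6, log = TRUE) - dnorm(prop, 0.75, 0.6, log = TRUE)
    if (log(runif(1)) < lacc) x <- prop
    om2[i] <- x
  }
  keep <- -(1:2000)
  expect_lt(abs(mean(og[keep]) - mean(om2[keep])), 0.02)
  expect_lt(abs(sd(og[keep]) - sd(om2[keep])), 0.02)
})

test_that("rescaling pins total variances at one and keeps signs", {
  rs <- rescale_draws(diag(2), diag(2), matrix(1, 3, 2))
  expect_equal(rs$Gamma, diag(2) / 2)
  expect_equal(rs$Psi, diag(2) / 2)
  expect_equal(diag(rs$Gamma) + diag(rs$Psi), c(1, 1))

  set.seed(58)
  for (rep in 1:50) {
    p <- sample(2:6, 1)
    G <- random_spd(p); P <- random_spd(p); B <- matrix(rnorm(4 * p), 4, p)
    rs <- rescale_draws(G, P, B)
    expect_equal(diag(rs$Gamma) + diag(rs$Psi), rep(1, p))
    expect_equal(sign(rs$Gamma[upper.tri(G)]), sign(G[upper.tri(G)]))
    # idempotent on already-rescaled input
    rs2 <- rescale_draws(rs$Gamma, rs$Psi, rs$B)
    expect_equal(rs2$Gamma, rs$Gamma)
    expect_equal(rs2$B, rs$B)
  }
})
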