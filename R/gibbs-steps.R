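#' Conditional draws of the block Gibbs sampler
#'
#' These functions implement the individual full-conditional updates; they are
#' composed by [mgcgm()] but exported so each kernel can be exercised and
#' checked in isolation.
#'
#' @name gibbs-steps
#' @keywords internal
NULL

#' Inverse-Gaussian random draws
#'
#' Michael-Schucany-Haas transformation method.
#'
#' @param n number of draws.
#' @param mean,shape distribution parameters (recycled), both positive.
#' @return numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  if (any(mean <= 0) || any(shape <= 0)) stop("mean and shape must be positive")
  mean <- rep_len(mean, n); shape <- rep_len(shape, n)
  y <- rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  x <- pmax(x, .Machine$double.xmin)
  u <- runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Inverse-Wishart random draw
#'
#' Bartlett decomposition: draws `W ~ Wishart(df, solve(S))` and returns
#' `solve(W)`.
#'
#' @param df degrees of freedom, `df > p - 1`.
#' @param S p x p SPD scale matrix.
#' @return one p x p SPD draw.
#' @export
rinvwishart <- function(df, S) {
  p <- nrow(S)
  if (df <= p - 1) stop("degrees of freedom must exceed p - 1")
  if (!is_spd(S)) stop("scale matrix must be SPD")
  L <- t(chol(.inv_spd(S)))                # lower factor of solve(S)
  A <- matrix(0, p, p)
  diag(A) <- sqrt(rchisq(p, df - seq_len(p) + 1))
  if (p > 1) A[lower.tri(A)] <- rnorm(p * (p - 1) / 2)
  LA <- L %*% A
  W <- tcrossprod(LA)
  .inv_spd(W)
}

#' Sample the cluster random effects
#'
#' For each cluster c with n_c rows, draws
#' `b_c ~ N((Psi^-1 + n_c Omega)^-1 Omega sum_i z_i, (Psi^-1 + n_c Omega)^-1)`.
#'
#' @param Z N x p latent matrix.
#' @param cluster integer cluster index per row (1..m).
#' @param omega p x p latent precision matrix.
#' @param psi p x p random-effect covariance.
#' @param m number of clusters.
#' @return m x p matrix of random-effect draws.
#' @export
sample_random_effects <- function(Z, cluster, omega, psi, m = max(cluster)) {
  p <- ncol(Z)
  nc <- tabulate(cluster, nbins = m)
  if (any(nc == 0L)) stop("every cluster must contain at least one row")
  psi_inv <- .inv_spd(psi)
  B <- matrix(0, m, p)
  zsum <- rowsum(Z, cluster)
  for (cc in seq_len(m)) {
    U <- .chol_spd(psi_inv + nc[cc] * omega)
    V <- chol2inv(U)                       # (Psi^-1 + n_c Omega)^-1
    mu <- V %*% (omega %*% zsum[cc, ])
    B[cc, ] <- mu + backsolve(U, rnorm(p))
  }
  B
}

#' Sample the random-effect covariance
#'
#' `Psi ~ InverseWishart(nu + m, Lambda + sum_c b_c b_c^T)`; with `m = 0` this
#' is a draw from the prior.
#'
#' @param B m x p matrix of current random effects (may have zero rows).
#' @param nu prior degrees of freedom.
#' @param Lambda p x p prior scale matrix.
#' @return one p x p SPD draw.
#' @export
sample_psi <- function(B, nu, Lambda) {
  rinvwishart(nu + nrow(B), .symmetrize(Lambda + crossprod(B)))
}

#' Sample the element-wise shrinkage parameters
#'
#' Off-diagonal entries follow `Gamma(1 + s, |omega_ij| + t)`, the conjugate
#' update under the double-exponential prior with a Gamma(s, t) hyperprior.
#' The diagonal shrinkage is held at the fixed constant `lambda_diag`
#' (exponential prior `Exp(omega_ii | lambda_diag / 2)`): adaptivity is only
#' applied across conditional associations.  A fully adaptive diagonal would
#' make the marginal prior tail on `omega_ii` polynomial of order `1 + s`,
#' which for small `s` cannot contain the near-degenerate directions that
#' arise when a rare binary variable is strongly coupled to the rest; the
#' fixed exponential diagonal keeps the precision matrix bounded.
#'
#' @param omega current p x p precision matrix.
#' @param s,t positive hyper-parameters of the Gamma(s, t) hyperprior.
#' @param lambda_diag fixed diagonal shrinkage constant (default 1).
#' @return symmetric p x p matrix of positive shrinkage parameters.
#' @export
sample_shrinkage <- function(omega, s, t, lambda_diag = 1) {
  if (s <= 0 || t <= 0) stop("s and t must be positive")
  if (lambda_diag <= 0) stop("lambda_diag must be positive")
  p <- nrow(omega)
  lam <- matrix(0, p, p)
  up <- upper.tri(omega)
  lam[up] <- rgamma(sum(up), shape = 1 + s, rate = abs(omega[up]) + t)
  lam <- lam + t(lam)
  diag(lam) <- lambda_diag
  lam
}

#' Sample the auxiliary scale matrix of the Laplace mixture
#'
#' Each off-diagonal `tau_ij` is the reciprocal of an inverse-Gaussian draw
#' with mean `lambda_ij / |omega_ij|` and shape `lambda_ij^2`, i.e. the
#' variance of the normal in the scale-mixture representation of the
#' double-exponential prior.  `|omega_ij|` is floored at 1e-10.
#'
#' @param omega current p x p precision matrix.
#' @param lam symmetric matrix of shrinkage parameters.
#' @return symmetric p x p matrix with zero diagonal, positive off-diagonals.
#' @export
sample_scaling <- function(omega, lam) {
  if (any(lam <= 0)) stop("shrinkage parameters must be positive")
  p <- nrow(omega)
  tau <- matrix(0, p, p)
  up <- upper.tri(omega)
  mu <- lam[up] / pmax(abs(omega[up]), 1e-10)
  tau[up] <- 1 / rinvgauss(sum(up), mean = mu, shape = lam[up]^2)
  tau + t(tau)
}

#' Column-wise precision update by data augmentation
#'
#' Partitions `omega` about column `l` and redraws that column/row:
#' `gamma ~ Gamma(N/2 + 1, (s22 + lambda22)/2)`,
#' `beta ~ N(-C s12, C)` with
#' `C = ((s22 + lambda22) Omega11^-1 + diag(1/tau12))^-1`, then
#' `omega_12 = beta` and `omega_22 = gamma + beta^T Omega11^-1 beta`, which is
#' SPD by construction (the Schur complement equals `gamma > 0`).
#'
#' @param omega current p x p SPD precision matrix.
#' @param S p x p cross-product matrix `sum (z - b)(z - b)^T`.
#' @param tau auxiliary scale matrix from [sample_scaling()].
#' @param lam shrinkage matrix from [sample_shrinkage()].
#' @param l column to update.
#' @param N number of rows contributing to `S`.
#' @return updated p x p SPD precision matrix.
#' @export
update_precision_column <- function(omega, S, tau, lam, l, N) {
  p <- nrow(omega)
  lam22 <- lam[l, l]
  s22 <- S[l, l]
  gam <- rgamma(1, shape = N / 2 + 1, rate = (s22 + lam22) / 2)
  if (p == 1L) return(matrix(gam, 1, 1))
  po <- partition_column(omega, l)
  O11_inv <- .inv_spd(po$M11)
  s12 <- S[-l, l]
  tau12 <- tau[-l, l]
  C <- .inv_spd((s22 + lam22) * O11_inv + diag(1 / tau12, p - 1))
  U <- .chol_spd(C)
  beta <- drop(-C %*% s12 + t(U) %*% rnorm(p - 1))
  om22 <- gam + drop(crossprod(beta, O11_inv %*% beta))
  .symmetrize(unpartition_column(po$M11, beta, om22, l))
}

#' Rescale a draw to the identified correlation scale
#'
#' The copula leaves the latent scale unidentified; entry (g, h) of the latent
#' covariance `Gamma_raw = solve(omega)` and of `Psi_raw` is divided by
#' `sqrt((Gamma_raw[g,g] + Psi_raw[g,g]) * (Gamma_raw[h,h] + Psi_raw[h,h]))`
#' and column g of `B_raw` by `sqrt(Gamma_raw[g,g] + Psi_raw[g,g])`, so that
#' the total marginal latent variance `diag(Gamma) + diag(Psi)` is 1.
#'
#' @param Gamma_raw p x p latent covariance (inverse of the current precision).
#' @param Psi_raw p x p random-effect covariance.
#' @param B_raw m x p random effects.
#' @return list with rescaled `Gamma`, `Psi`, `B` and the scale factors `d`
#'   (the total variances divided out).
#' @export
rescale_draws <- function(Gamma_raw, Psi_raw, B_raw) {
  d <- diag(Gamma_raw) + diag(Psi_raw)
  if (any(d <= 0)) stop("total marginal variances must be positive")
  sc <- 1 / sqrt(d)
  D <- tcrossprod(sc)
  list(Gamma = Gamma_raw * D, Psi = Psi_raw * D,
       B = sweep(B_raw, 2, sc, `*`), d = d)
}
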