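#' Deterministic linear-algebra helpers shared by the sampler and summaries
#'
#' @name model-core
#' @keywords internal
NULL

.is_symmetric <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * (1 + max(abs(M)))
}

#' Check symmetric positive definiteness
#'
#' A matrix passes when its minimum eigenvalue exceeds `1e-10` times its
#' largest eigenvalue, a guard against floating-point drift over long runs.
#'
#' @param M square numeric matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_spd <- function(M) {
  if (!.is_symmetric(M)) return(FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > 1e-10 * max(abs(ev[1]), .Machine$double.eps)
}

.symmetrize <- function(M) (M + t(M)) / 2

# Guarded Cholesky: near the positive-definite boundary (conditional
# associations approaching 1 in magnitude) plain chol() can fail from
# round-off; escalate a tiny ridge until it succeeds.
.chol_spd <- function(M) {
  M <- .symmetrize(M)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  d <- mean(abs(diag(M))) + .Machine$double.eps
  for (k in -10:-1) {
    ch <- tryCatch(chol(M + 10^k * d * diag(nrow(M))),
                   error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("matrix is numerically indefinite beyond repair")
}

.inv_spd <- function(M) .symmetrize(chol2inv(.chol_spd(M)))

#' Partition a symmetric matrix about one column
#'
#' Permutes row/column `l` to the last position and returns the resulting
#' blocks: the leading (p-1) x (p-1) block, the off-diagonal vector and the
#' scalar corner.  This is the block decomposition used by the column-wise
#' precision update.
#'
#' @param M symmetric p x p matrix.
#' @param l column index in 1..p.
#' @return list with `M11` ((p-1) x (p-1)), `m12` (length p-1), `m22` (scalar)
#'   and `perm`, the permutation applied (so callers can map back).
#' @export
#' @examples
#' partition_column(diag(3), 2)
partition_column <- function(M, l) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be square")
  if (!.is_symmetric(M)) stop("M must be symmetric")
  p <- nrow(M)
  if (l < 1 || l > p) stop("column index out of range")
  perm <- c(seq_len(p)[-l], l)
  Mp <- M[perm, perm, drop = FALSE]
  list(M11 = Mp[-p, -p, drop = FALSE], m12 = Mp[-p, p], m22 = Mp[p, p],
       perm = perm)
}

#' Reassemble a matrix from its column partition
#'
#' Exact inverse of [partition_column()].
#'
#' @param M11,m12,m22 blocks as returned by [partition_column()].
#' @param l the column index that was moved last.
#' @return the original p x p symmetric matrix.
#' @export
unpartition_column <- function(M11, m12, m22, l) {
  p <- nrow(M11) + 1L
  Mp <- rbind(cbind(M11, m12), c(m12, m22))
  perm <- c(seq_len(p)[-l], l)
  inv <- order(perm)
  unname(Mp[inv, inv, drop = FALSE])
}

#' Conditional (regression-type) coefficients of one variable on the rest
#'
#' For a latent Gaussian vector with covariance `Gamma`, the conditional mean
#' of variable `l` given the others is linear with coefficient vector
#' `solve(Gamma[-l,-l]) %*% Gamma[-l,l]`, identically `-Omega[l,-l]/Omega[l,l]`
#' in terms of the precision matrix `Omega = solve(Gamma)`.
#'
#' @param Gamma symmetric positive-definite covariance matrix.
#' @param l response index.
#' @return numeric vector of length `p - 1`, named after the remaining
#'   variables when `Gamma` has dimnames.
#' @export
conditional_coefficients <- function(Gamma, l) {
  p <- nrow(Gamma)
  if (l < 1 || l > p) stop("response index out of range")
  cf <- tryCatch(solve(Gamma[-l, -l, drop = FALSE], Gamma[-l, l]),
                 error = function(e) stop("singular covariance matrix"))
  nm <- colnames(Gamma)
  if (!is.null(nm)) names(cf) <- nm[-l]
  drop(cf)
}

#' Partial correlation matrix from a precision matrix
#'
#' Standardizes a precision matrix for edge ranking: the off-diagonal (i, j)
#' entry is `-omega_ij / sqrt(omega_ii * omega_jj)` and the diagonal is 1.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return p x p partial correlation matrix.
#' @export
partial_correlation <- function(omega) {
  d <- diag(omega)
  if (any(d <= 0)) stop("precision matrix must have positive diagonal")
  s <- 1 / sqrt(d)
  R <- -omega * tcrossprod(s)
  diag(R) <- 1
  R
}
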