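#' Maximum a posteriori precision matrix under a common fixed shrinkage
#'
#' With a common fixed shrinkage parameter `lambda` (adaptivity disabled), no
#' random effects and fully observed continuous data, the log-posterior over
#' the precision matrix is, up to constants and a factor N/2,
#' `log det(Omega) - tr(S_N Omega) - (lambda/N) ||Omega||_1` with `S_N` the
#' sample second-moment matrix, i.e. the L1-penalized Gaussian log-likelihood
#' at penalty `rho = lambda / N`.  This function maximizes it by proximal
#' gradient ascent (soft-thresholding prox, backtracking line search that
#' also enforces positive definiteness).
#'
#' @param x N x p matrix of (mean-zero) observations, or a p x p sample
#'   second-moment matrix if `N` is supplied.
#' @param lambda common shrinkage parameter (> 0).
#' @param N number of observations (required when `x` is already a matrix of
#'   sufficient statistics).
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @return the p x p SPD maximizer.
#' @export
precision_map <- function(x, lambda, N = NULL, max_iter = 10000, tol = 1e-10) {
  if (is.null(N)) {
    N <- nrow(x)
    S <- crossprod(x) / N
  } else {
    S <- x / N
  }
  if (lambda <= 0) stop("lambda must be positive")
  p <- ncol(S)
  rho <- lambda / N
  soft <- function(M, a) sign(M) * pmax(abs(M) - a, 0)
  obj <- function(Om, ch) {
    2 * sum(log(diag(ch))) - sum(S * Om) - rho * sum(abs(Om))
  }
  Om <- diag(1 / (diag(S) + rho), p)
  ch <- chol(Om)
  f <- obj(Om, ch)
  step <- 1
  for (it in seq_len(max_iter)) {
    grad <- chol2inv(ch) - S            # gradient of the smooth part
    repeat {
      cand <- .symmetrize(soft(Om + step * grad, step * rho))
      chc <- tryCatch(chol(cand), error = function(e) NULL)
      if (!is.null(chc)) {
        fc <- obj(cand, chc)
        if (fc >= f - 1e-12) break
      }
      step <- step / 2
      if (step < 1e-14) return(Om)
    }
    delta <- max(abs(cand - Om)) / max(1, max(abs(Om)))
    Om <- cand; ch <- chc; f <- fc
    step <- min(step * 1.5, 10)
    if (delta < tol) break
  }
  Om
}
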