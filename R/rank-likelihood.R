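#' Truncation bounds for one latent cell under the extended rank likelihood
#'
#' The latent value of an observed cell must stay between the largest current
#' latent value among rows with a strictly smaller observation and the
#' smallest among rows with a strictly larger one, pooled over all N rows.
#' Ties impose no constraint and rows with a missing observation contribute
#' to neither extremum.
#'
#' @param y_col observed column (length N, `NA` for missing).
#' @param z_col current latent column (length N).
#' @param row index of the cell being updated; must be observed.
#' @return `c(lb, ub)`, possibly `-Inf`/`Inf`.
#' @export
rank_bounds <- function(y_col, z_col, row) {
  if (is.na(y_col[row])) stop("row refers to a missing cell; use the untruncated update")
  y0 <- y_col[row]
  below <- !is.na(y_col) & y_col < y0
  above <- !is.na(y_col) & y_col > y0
  c(if (any(below)) max(z_col[below]) else -Inf,
    if (any(above)) min(z_col[above]) else Inf)
}

#' Draw from a (possibly truncated) normal distribution
#'
#' Inverse-CDF sampling with log-space tail computation, falling back to
#' rejection when the truncation interval mass underflows; with infinite
#' bounds this is an ordinary normal draw.  Used for every latent-cell update.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (recycled).
#' @param lb,ub truncation bounds (recycled); `lb < ub` required.
#' @return numeric vector of `n` draws inside `(lb, ub)`.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lb = -Inf, ub = Inf) {
  if (any(sd <= 0)) stop("sd must be positive")
  rtnorm_cpp(as.integer(n), as.numeric(mean), as.numeric(sd),
             as.numeric(lb), as.numeric(ub))
}

# Per-column scan structure for the latent sweep: observed rows sorted by
# (level, storage order), block offsets per level, and missing rows.  Depends
# only on the observed data, so it is computed once per fit.
.column_scan_info <- function(data) {
  p <- ncol(data$values)
  ord <- starts <- miss <- vector("list", p)
  for (l in seq_len(p)) {
    y <- data$values[, l]
    obs <- which(!is.na(y))
    lev <- as.integer(factor(y[obs]))        # dense ranks 1..k
    o <- obs[order(lev, obs)]
    ord[[l]] <- o - 1L
    nlev <- if (length(obs)) max(lev) else 0L
    starts[[l]] <- c(0L, cumsum(tabulate(lev, nbins = nlev)))
    miss[[l]] <- which(is.na(y)) - 1L
  }
  list(ord = ord, starts = starts, miss = miss)
}

#' One Gibbs sweep over the latent matrix
#'
#' Redraws every cell of the latent matrix from its conditional normal given
#' the other coordinates of the same row and the row's cluster effect:
#' truncated to the rank-consistent interval for observed cells, untruncated
#' for missing cells.  Cells are visited column by column, within a column in
#' increasing order of observed level (storage order within a level), with
#' truncation bounds recomputed from the current latent values as the scan
#' proceeds, so the rank ordering holds on exit.
#'
#' @param data a [mixed_data] object.
#' @param z N x p latent matrix.
#' @param Gamma p x p latent covariance (SPD).
#' @param B m x p cluster random effects.
#' @param scan optional precomputed scan structure (internal reuse).
#' @return updated N x p latent matrix.
#' @export
latent_sweep <- function(data, z, Gamma, B, scan = NULL) {
  p <- ncol(z)
  if (p == 1L) {
    omega <- matrix(1 / Gamma[1, 1], 1, 1)
  } else {
    if (!is_spd(Gamma)) stop("Gamma must be symmetric positive definite")
    omega <- .inv_spd(Gamma)
  }
  if (is.null(scan)) scan <- .column_scan_info(data)
  wv <- .cond_weights(omega)
  latent_sweep_cpp(z, data$cluster - 1L, as.matrix(B), wv$w, wv$v,
                   scan$ord, scan$starts, scan$miss)
}

# Conditional-mean weights and variances from a precision matrix:
# w[l, j] = -omega_lj / omega_ll (j != l), v[l] = 1 / omega_ll.
.cond_weights <- function(omega) {
  d <- diag(omega)
  w <- -omega / d
  diag(w) <- 0
  list(w = w, v = 1 / d)
}
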