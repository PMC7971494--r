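#' Synthetic multilevel mixed-type data
#'
#' Generators emulating the latent-Gaussian multilevel model: cluster effects
#' `b_c ~ N(0, Psi)`, latent rows `z_ic ~ N(b_c, solve(Omega))`, cluster sizes
#' Poisson, optional discretization into ordinal/binary columns and optional
#' MCAR/MAR missingness.  All functions draw from R's current RNG stream, so
#' `set.seed()` makes them reproducible.
#'
#' @name synthetic
NULL

#' True parameter matrices of the built-in calibration design
#'
#' The fixed 4-variable configuration used by [coverage_study()]: a
#' random-effect covariance `Psi` and latent precision `Omega` whose total
#' marginal latent variances `diag(solve(Omega)) + diag(Psi)` equal 1, so the
#' truth lies on the identified copula scale.  `omega_13 = 0.067` and
#' `omega_34 = 0.046` are deliberately weak conditional associations whose
#' interval coverage degrades as the shrinkage hyper-parameter `t` shrinks.
#'
#' @return list with `Psi` and `Omega` (both 4 x 4 SPD).
#' @export
calibration_truth <- function() {
  Psi <- matrix(c(0.562, 0.090, 0.140, -0.028,
                  0.090, 0.212, 0.053, 0.030,
                  0.140, 0.053, 0.379, 0.050,
                  -0.028, 0.030, 0.050, 0.505), 4, 4)
  Omega <- matrix(c(3.183, -0.918, 0.067, 1.209,
                    -0.918, 1.545, -0.028, -0.498,
                    0.067, -0.028, 1.613, 0.046,
                    1.209, -0.498, 0.046, 2.497), 4, 4)
  list(Psi = Psi, Omega = Omega)
}

#' Simulate the latent multilevel Gaussian layer
#'
#' Cluster sizes are Poisson(`cluster_size_mean`), redrawn when 0 (an empty
#' cluster is invalid for the random-effect update); `b_c ~ N(0, Psi_true)`
#' and rows `z ~ N(b_c, solve(Omega_true))`.
#'
#' @param m number of clusters.
#' @param cluster_size_mean Poisson mean of the cluster sizes.
#' @param Omega_true p x p SPD latent precision matrix.
#' @param Psi_true p x p SPD random-effect covariance.
#' @return list with `Z` (N x p), `cluster` (length N, values 1..m),
#'   `B_true` (m x p) and `sizes`.
#' @export
simulate_latent <- function(m, cluster_size_mean, Omega_true, Psi_true) {
  if (!is_spd(Omega_true) || !is_spd(Psi_true))
    stop("Omega_true and Psi_true must be SPD")
  sizes <- rpois(m, cluster_size_mean)
  while (any(sizes == 0L)) sizes[sizes == 0L] <- rpois(sum(sizes == 0L),
                                                       cluster_size_mean)
  cluster <- rep(seq_len(m), sizes)
  B_true <- .rmvnorm(m, Psi_true)
  Sigma <- chol2inv(chol(Omega_true))
  Z <- B_true[cluster, , drop = FALSE] + .rmvnorm(length(cluster), Sigma)
  list(Z = Z, cluster = cluster, B_true = B_true, sizes = sizes)
}

#' One replicate of the calibration design
#'
#' 20 clusters with Poisson(50) sizes, four continuous columns generated from
#' the [calibration_truth()] matrices, no missingness.
#'
#' @param m number of clusters (default 20).
#' @param cluster_size_mean Poisson mean of cluster sizes (default 50).
#' @return a [mixed_data] object with attribute `"truth"` carrying the
#'   generating matrices and cluster effects.
#' @export
simulate_calibration_data <- function(m = 20, cluster_size_mean = 50) {
  tr <- calibration_truth()
  sim <- simulate_latent(m, cluster_size_mean, tr$Omega, tr$Psi)
  colnames(sim$Z) <- paste0("V", 1:4)
  out <- mixed_data(sim$Z, "continuous", sim$cluster)
  attr(out, "truth") <- c(tr, list(B_true = sim$B_true))
  out
}

#' Discretize latent columns into ordinal/binary variables
#'
#' Binary columns are cut at one empirical quantile, ordinal columns at k - 1
#' quantiles, continuous columns pass through, so the discretized ranks are
#' coarsenings of the latent ranks (the discretization depends on the latent
#' column only through its ranks).
#'
#' @param Z N x p latent matrix.
#' @param cluster per-row cluster labels.
#' @param types per-column type in `continuous`/`ordinal`/`binary`.
#' @param thresholds list with one numeric vector of strictly increasing
#'   quantile probabilities in (0, 1) per non-continuous column (a single
#'   probability for binary, k - 1 for a k-level ordinal); entries for
#'   continuous columns are ignored.
#' @param cohort_of_cluster passed through to [mixed_data()].
#' @return a [mixed_data] object.
#' @export
discretize_latent <- function(Z, cluster, types, thresholds,
                              cohort_of_cluster = NULL) {
  p <- ncol(Z)
  types <- if (length(types) == 1L) rep(types, p) else types
  vals <- Z
  if (is.null(colnames(vals))) colnames(vals) <- paste0("V", seq_len(p))
  for (l in seq_len(p)) {
    if (types[l] == "continuous") next
    th <- thresholds[[l]]
    if (is.null(th)) stop(sprintf("no thresholds for column %d", l))
    if (any(th <= 0) || any(th >= 1)) stop("thresholds must lie in (0, 1)")
    if (is.unsorted(th, strictly = TRUE)) stop("thresholds must be strictly increasing")
    if (types[l] == "binary" && length(th) != 1L)
      stop("binary columns take exactly one threshold")
    cuts <- quantile(Z[, l], th, names = FALSE, type = 7)
    vals[, l] <- findInterval(Z[, l], cuts, left.open = TRUE)
  }
  mixed_data(vals, types, cluster, cohort_of_cluster)
}

#' Inject missing cells
#'
#' `MCAR` blanks cells with constant probability `rate`.  `MAR` blanks cells
#' with probability increasing in a fully observed driver column through a
#' logistic link on the standardized driver, with the intercept solved so the
#' expected missing fraction equals `rate`; the driver column itself is never
#' blanked.
#'
#' @param data a [mixed_data] object.
#' @param rate target missing fraction, `0 <= rate < 1`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param driver column name or index of the MAR driver (required for MAR).
#' @param slope logistic slope on the standardized driver (default 1).
#' @return the dataset with additional `NA` cells.
#' @export
inject_missing <- function(data, rate, mechanism = c("MCAR", "MAR"),
                           driver = NULL, slope = 1) {
  stopifnot(inherits(data, "mixed_data"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  mechanism <- match.arg(mechanism)
  if (rate == 0) return(data)
  vals <- data$values
  N <- nrow(vals); p <- ncol(vals)
  if (mechanism == "MCAR") {
    drop <- matrix(runif(N * p) < rate, N, p)
  } else {
    if (is.null(driver)) stop("MAR requires a driver column")
    di <- if (is.character(driver)) match(driver, colnames(vals)) else as.integer(driver)
    if (is.na(di)) stop("driver column not found")
    x <- vals[, di]
    if (anyNA(x)) stop("the MAR driver column must be fully observed")
    xs <- as.numeric(scale(x))
    a <- uniroot(function(a0) mean(plogis(a0 + slope * xs)) - rate,
                 c(-50, 50))$root
    pr <- plogis(a + slope * xs)
    drop <- matrix(runif(N * p) < pr, N, p)   # recycles pr down each column
    drop[, di] <- FALSE
  }
  vals[drop] <- NA
  mixed_data(vals, data$types, data$cluster_labels[data$cluster],
             data$cohort_of_cluster)
}
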