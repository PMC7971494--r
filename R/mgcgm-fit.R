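#' Fit a multilevel Gaussian copula graphical model
#'
#' Runs the block Gibbs sampler for the Gaussian copula graphical model with
#' an adaptive graphical lasso prior on the latent precision matrix and
#' cluster-level Gaussian random effects.  Marginals are handled by the
#' extended rank likelihood, so only the ordering of each observed column
#' enters the fit; missing cells are integrated over.
#'
#' Each iteration cycles through: the cluster random effects, their
#' covariance (inverse-Wishart), the element-wise shrinkage parameters
#' (Gamma), the Laplace-mixture scales (reciprocal inverse-Gaussian), a
#' column-wise precision update, a rescaling that pins the unidentified
#' copula scale so the total marginal latent variance is 1, and a truncated
#' normal sweep over the latent matrix.  The rescaled state is both stored
#' and carried forward, so all reported draws live on the identified scale.
#'
#' @param data a [mixed_data] object.
#' @param s,t positive hyper-parameters of the Gamma(s, t) hyperprior on the
#'   element-wise shrinkage parameters.  Defaults `s = 0.01`, `t = 1e-4`;
#'   smaller `t` means stronger shrinkage of weak conditional associations.
#' @param lambda_diag fixed diagonal shrinkage constant (see
#'   [sample_shrinkage()]); default 1.
#' @param nu inverse-Wishart prior degrees of freedom for the random-effect
#'   covariance; default `p + 2`.
#' @param Lambda inverse-Wishart prior scale; default identity.
#' @param n_iter total Gibbs iterations per chain (default 20000).
#' @param thin keep every `thin`-th iteration (default 10).
#' @param burn_frac fraction of iterations discarded as burn-in (default 0.5).
#' @param n_chains number of independent chains (default 1; use >= 2 for
#'   convergence diagnostics).
#' @param seed integer seed; chain k uses `seed + k - 1`.
#' @param store_z keep the latent matrix at saved iterations (needed by
#'   [predict.mgcgm()]).
#' @param latent_update update the latent matrix by the truncated-normal rank
#'   sweep (default `TRUE`, the extended-rank-likelihood model).  With
#'   `FALSE` the latent matrix is fixed at the observed values, which
#'   requires fully observed continuous data whose columns are already on
#'   the latent Gaussian scale; used by [coverage_study()], where the
#'   generated columns are the latent Gaussians themselves.
#' @param verbose print progress every 500 iterations.
#' @return an object of class `mgcgm`: a list with `draws` (arrays `Gamma`,
#'   `Omega`, `Psi` of dim K x p x p, `B` of dim K x m x p, optionally `Z`),
#'   `chain` (chain index per saved draw), `psrf` (per-parameter potential
#'   scale reduction factors when `n_chains >= 2`), `data` and `settings`.
#' @seealso [summary.mgcgm()], [coef.mgcgm()], [predict.mgcgm()],
#'   [top_edges()], [cohort_contrast()], [coverage_study()]
#' @export
mgcgm <- function(data, s = 0.01, t = 1e-4, lambda_diag = 1,
                  nu = NULL, Lambda = NULL,
                  n_iter = 20000, thin = 10, burn_frac = 0.5, n_chains = 1,
                  seed = 1, store_z = FALSE, latent_update = TRUE,
                  verbose = FALSE) {
  stopifnot(inherits(data, "mixed_data"))
  if (!latent_update &&
      (any(data$missing) || any(data$types != "continuous")))
    stop("latent_update = FALSE requires fully observed continuous data")
  p <- ncol(data$values)
  if (is.null(nu)) nu <- p + 2
  if (is.null(Lambda)) Lambda <- diag(p)
  if (s <= 0 || t <= 0) stop("s and t must be positive")
  if (nu <= p - 1) stop("nu must exceed p - 1")
  settings <- list(s = s, t = t, lambda_diag = lambda_diag,
                   nu = nu, Lambda = Lambda, n_iter = n_iter,
                   thin = thin, burn_frac = burn_frac, n_chains = n_chains,
                   seed = seed, store_z = store_z, latent_update = latent_update)
  chains <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    chains[[k]] <- .run_chain(data, settings, chain = k, verbose = verbose)
  }
  draws <- list(
    Gamma = .abind1(lapply(chains, `[[`, "Gamma")),
    Omega = .abind1(lapply(chains, `[[`, "Omega")),
    Psi   = .abind1(lapply(chains, `[[`, "Psi")),
    B     = .abind1(lapply(chains, `[[`, "B")))
  if (store_z) draws$Z <- .abind1(lapply(chains, `[[`, "Z"))
  K_each <- vapply(chains, function(ch) dim(ch$Omega)[1], integer(1))
  fit <- structure(list(
    draws = draws,
    chain = rep(seq_len(n_chains), K_each),
    psrf = NULL, data = data, settings = settings), class = "mgcgm")
  if (n_chains >= 2) fit$psrf <- psrf_table(fit)
  fit
}

.run_chain <- function(data, st, chain, verbose = FALSE) {
  set.seed(st$seed + chain - 1L)
  Y <- data$values
  N <- nrow(Y); p <- ncol(Y)
  m <- length(data$cluster_labels)
  scan <- .column_scan_info(data)

  if (st$latent_update) {
    # normal-scores initialization keeps Z inside the rank event from the start
    Z <- matrix(rnorm(N * p), N, p)
    for (l in seq_len(p)) {
      obs <- !is.na(Y[, l])
      if (any(obs)) {
        r <- rank(Y[obs, l], ties.method = "average")
        Z[obs, l] <- qnorm(r / (sum(obs) + 1))
      }
    }
  } else {
    Z <- Y                                 # observed Gaussian latents
  }
  Omega <- diag(p)
  if (chain > 1L) Omega <- Omega * exp(runif(1, -0.5, 0.5))  # overdispersed start

  burn <- floor(st$n_iter * st$burn_frac)
  raw <- run_chain_cpp(Z, data$cluster - 1L, m, st$s, st$t, st$lambda_diag,
                       st$nu, st$Lambda, st$n_iter, st$thin, burn,
                       st$store_z, st$latent_update,
                       scan$ord, scan$starts, scan$miss, Omega)
  out <- lapply(raw, function(a) aperm(a, c(3, 1, 2)))
  if (verbose)
    message(sprintf("chain %d: %d iterations, %d saved draws",
                    chain, st$n_iter, dim(out$Omega)[1]))
  out
}

.abind1 <- function(lst) {
  d <- dim(lst[[1]])
  K <- sum(vapply(lst, function(x) dim(x)[1], integer(1)))
  out <- array(NA_real_, c(K, d[2], d[3]))
  at <- 0L
  for (x in lst) {
    k <- dim(x)[1]
    out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

#' Potential scale reduction factors across chains
#'
#' Classic Gelman-Rubin diagnostic (between/within chain variances, no
#' split-chain refinement) for every unique entry of the precision and
#' random-effect covariance matrices.
#'
#' @param fit an `mgcgm` fit with at least two chains, or a list of numeric
#'   matrices (one per chain, draws in rows, parameters in columns).
#' @return for a fit, a data.frame with columns `parameter`, `matrix` and
#'   `psrf`; for a list of matrices, a numeric vector of PSRFs per column.
#' @export
psrf_table <- function(fit) {
  if (!inherits(fit, "mgcgm")) return(.psrf(fit))
  p <- dim(fit$draws$Omega)[2]
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  nm <- colnames(fit$data$values)
  flat <- function(arr)
    vapply(seq_len(nrow(ut)),
           function(k) arr[, ut[k, 1], ut[k, 2]], numeric(dim(arr)[1]))
  res <- list()
  for (mat in c("Omega", "Psi")) {
    X <- flat(fit$draws[[mat]])
    by_chain <- lapply(split(seq_len(nrow(X)), fit$chain),
                       function(i) X[i, , drop = FALSE])
    res[[mat]] <- data.frame(
      parameter = paste0(tolower(mat), "[", nm[ut[, 1]], ",", nm[ut[, 2]], "]"),
      matrix = mat, psrf = .psrf(by_chain))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.psrf <- function(chains) {
  M <- length(chains)
  if (M < 2) stop("at least two chains are required for the PSRF")
  n <- nrow(chains[[1]])
  means <- sapply(chains, colMeans)
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  vars <- sapply(chains, function(x) apply(x, 2, var))
  if (is.null(dim(vars))) vars <- matrix(vars, nrow = 1)
  W <- rowMeans(vars)
  Bn <- apply(means, 1, var) * n
  vhat <- (n - 1) / n * W + Bn / n
  out <- sqrt(vhat / W)
  out[W == 0 & Bn == 0] <- 1        # frozen identical chains
  out
}

#' @export
print.mgcgm <- function(x, ...) {
  st <- x$settings
  K <- dim(x$draws$Omega)[1]
  cat(sprintf("Multilevel Gaussian copula graphical model (%d variables, %d clusters)\n",
              dim(x$draws$Omega)[2], dim(x$draws$B)[2]))
  cat(sprintf("  adaptive graphical lasso prior: s = %g, t = %g\n", st$s, st$t))
  cat(sprintf("  %d chain(s) x %d iterations, thin %d, burn-in %d%%: %d saved draws\n",
              st$n_chains, st$n_iter, st$thin, round(100 * st$burn_frac), K))
  if (!is.null(x$psrf))
    cat(sprintf("  parameters with PSRF > 1.05: %.1f%% (Omega), %.1f%% (Psi)\n",
                100 * mean(x$psrf$psrf[x$psrf$matrix == "Omega"] > 1.05),
                100 * mean(x$psrf$psrf[x$psrf$matrix == "Psi"] > 1.05)))
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object an `mgcgm` fit.
#' @param ... unused.
#' @return a `summary.mgcgm` list with posterior means of the precision,
#'   latent covariance and random-effect covariance, total-variance check and
#'   convergence summary.
#' @export
summary.mgcgm <- function(object, ...) {
  nm <- colnames(object$data$values)
  mean2 <- function(a) {
    M <- apply(a, c(2, 3), mean)
    dimnames(M) <- list(nm, nm)
    M
  }
  out <- list(
    omega_mean = mean2(object$draws$Omega),
    gamma_mean = mean2(object$draws$Gamma),
    psi_mean = mean2(object$draws$Psi),
    pcor_mean = partial_correlation(mean2(object$draws$Omega)),
    total_variance = diag(mean2(object$draws$Gamma)) + diag(mean2(object$draws$Psi)),
    psrf = object$psrf, settings = object$settings,
    n_draws = dim(object$draws$Omega)[1])
  class(out) <- "summary.mgcgm"
  out
}

#' @export
print.summary.mgcgm <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summaries from %d saved draws\n", x$n_draws))
  cat("\nPosterior mean precision matrix (Omega):\n")
  print(round(x$omega_mean, digits))
  cat("\nPosterior mean random-effect covariance (Psi):\n")
  print(round(x$psi_mean, digits))
  cat("\nTotal marginal latent variances (should be 1 by construction):\n")
  print(round(x$total_variance, digits))
  if (!is.null(x$psrf))
    cat(sprintf("\nPSRF > 1.05: %.1f%% of parameters\n",
                100 * mean(x$psrf$psrf > 1.05)))
  invisible(x)
}

#' Posterior mean coefficients
#'
#' With `response = NULL`, returns the posterior mean precision matrix.  With
#' a response named or indexed, returns the posterior mean conditional
#' (regression-type) coefficients of the other variables on that response;
#' see [association_report()] for interval summaries.
#'
#' @param object an `mgcgm` fit.
#' @param response optional column name or index.
#' @param ... unused.
#' @export
coef.mgcgm <- function(object, response = NULL, ...) {
  if (is.null(response)) {
    nm <- colnames(object$data$values)
    M <- apply(object$draws$Omega, c(2, 3), mean)
    dimnames(M) <- list(nm, nm)
    return(M)
  }
  rep <- association_report(object, response)
  setNames(rep$mean, rep$predictor)
}

#' Trace and graph plots for a fitted model
#'
#' `type = "trace"` draws traceplots of selected precision-matrix entries;
#' `type = "graph"` draws the sparse conditional-dependence graph of
#' [top_edges()] (positive associations red, negative blue).
#'
#' @param x an `mgcgm` fit.
#' @param type `"trace"` or `"graph"`.
#' @param pars for traces, matrix of index pairs (rows `c(i, j)`); default the
#'   first min(4, p(p+1)/2) upper-triangular entries.
#' @param quantile_frac for graphs, fraction of edges kept (default 0.03).
#' @param ... passed to the underlying plotting functions.
#' @export
plot.mgcgm <- function(x, type = c("trace", "graph"), pars = NULL,
                       quantile_frac = 0.03, ...) {
  type <- match.arg(type)
  nm <- colnames(x$data$values)
  if (type == "trace") {
    if (is.null(pars)) {
      ut <- which(upper.tri(diag(length(nm)), diag = TRUE), arr.ind = TRUE)
      pars <- ut[seq_len(min(4, nrow(ut))), , drop = FALSE]
    }
    old <- graphics::par(mfrow = c(nrow(pars), 1), mar = c(2.5, 4, 1, 1))
    on.exit(graphics::par(old))
    for (k in seq_len(nrow(pars))) {
      i <- pars[k, 1]; j <- pars[k, 2]
      graphics::plot(x$draws$Omega[, i, j], type = "l",
                     ylab = sprintf("omega[%s,%s]", nm[i], nm[j]),
                     xlab = "", ...)
    }
  } else {
    ed <- top_edges(x, quantile_frac = quantile_frac)
    if (nrow(ed) == 0) {
      warning("no edges selected; nothing to plot")
      return(invisible(NULL))
    }
    g <- .edges_to_igraph(ed)
    igraph::plot.igraph(g, edge.color = ifelse(igraph::E(g)$sign > 0,
                                               "red", "blue"), ...)
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Generates new datasets of the same shape as the fitted data from the
#' posterior mean latent precision and random-effect covariance, then
#' discretizes each ordinal/binary column at the empirical level frequencies
#' of the observed column.
#'
#' @param object an `mgcgm` fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [mixed_data] objects.
#' @export
simulate.mgcgm <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  omega <- apply(object$draws$Omega, c(2, 3), mean)
  psi <- apply(object$draws$Psi, c(2, 3), mean)
  Y <- object$data$values
  cl <- object$data$cluster
  m <- length(object$data$cluster_labels)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    Bt <- .rmvnorm(m, psi)
    Zs <- Bt[cl, , drop = FALSE] + .rmvnorm(nrow(Y), chol2inv(chol(omega)))
    vals <- Zs
    colnames(vals) <- colnames(Y)
    for (l in seq_len(ncol(Y))) {
      if (object$data$types[l] == "continuous") next
      obs <- Y[!is.na(Y[, l]), l]
      lev <- sort(unique(obs))
      cuts <- quantile(Zs[, l], cumsum(table(obs) / length(obs)))
      vals[, l] <- lev[1L + findInterval(Zs[, l], cuts[-length(cuts)],
                                         left.open = TRUE)]
    }
    out[[r]] <- mixed_data(vals, object$data$types,
                           object$data$cluster_labels[cl],
                           object$data$cohort_of_cluster)
  }
  if (nsim == 1) out[[1]] else out
}

.rmvnorm <- function(n, Sigma) {
  p <- nrow(Sigma)
  matrix(rnorm(n * p), n, p) %*% chol(.symmetrize(Sigma))
}
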