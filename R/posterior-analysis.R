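#' Highest density region of a posterior sample
#'
#' The shortest contiguous interval containing `ceiling(mass * K)` of the `K`
#' sorted draws (empirical HDR for a unimodal posterior).
#'
#' @param samples numeric vector of at least 50 draws.
#' @param mass coverage mass in (0, 1), default 0.95.
#' @return `c(lo, hi)`.
#' @export
hdr <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  K <- length(samples)
  if (K < 50) stop("too few samples for an HDR (need >= 50)")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  k <- ceiling(mass * K)
  s <- sort(samples)
  i <- which.min(s[k:K] - s[seq_len(K - k + 1)])
  c(s[i], s[i + k - 1])
}

#' Cohort contrasts of the cluster random effects
#'
#' For each variable, the per-draw unweighted mean of the cluster effects in
#' each cohort is differenced (first cohort minus second); the posterior
#' mean, 95% HDR and a flag for HDRs excluding 0 are reported.
#'
#' @param fit an `mgcgm` fit on data whose clusters carry a cohort map.
#' @param cohorts length-2 character vector naming the cohorts to contrast;
#'   default the first two cohort labels in the map.
#' @param mass HDR mass (default 0.95).
#' @return data.frame with `variable`, `mean`, `lo`, `hi`, `flag`.
#' @export
cohort_contrast <- function(fit, cohorts = NULL, mass = 0.95) {
  co <- fit$data$cohort_of_cluster
  if (is.null(co)) stop("the fitted data carry no cohort map")
  if (is.null(cohorts)) cohorts <- unique(unname(co))[1:2]
  cl_of <- co[fit$data$cluster_labels]
  g1 <- which(cl_of == cohorts[1])
  g2 <- which(cl_of == cohorts[2])
  if (!length(g1) || !length(g2)) stop("each cohort needs at least one cluster")
  B <- fit$draws$B
  nm <- colnames(fit$data$values)
  out <- data.frame(variable = nm, mean = NA_real_, lo = NA_real_,
                    hi = NA_real_, flag = FALSE)
  for (l in seq_along(nm)) {
    d <- apply(B[, g1, l, drop = FALSE], 1, mean) -
      apply(B[, g2, l, drop = FALSE], 1, mean)
    h <- hdr(d, mass)
    out$mean[l] <- mean(d); out$lo[l] <- h[1]; out$hi[l] <- h[2]
    out$flag[l] <- h[1] > 0 || h[2] < 0
  }
  out
}

#' Select the strongest conditional-dependence edges
#'
#' Ranks the p(p-1)/2 upper-triangular entries of the posterior mean
#' precision matrix by absolute value and keeps the top
#' `floor(quantile_frac * p(p-1)/2)`, labelled by the sign of the implied
#' association (negative precision entry = positive partial correlation).
#' Candidates whose posterior mean is exactly 0 are never selected (the
#' degenerate all-diagonal case yields an empty list with a warning).
#'
#' @param fit an `mgcgm` fit, or a K x p x p array of precision draws.
#' @param quantile_frac fraction of candidate pairs kept (default 0.03).
#' @param method rank by raw `|omega_ij|` (`"omega"`, default) or by the
#'   partial correlation magnitude (`"pcor"`).
#' @return data.frame with `from`, `to`, `weight` (posterior mean omega),
#'   `pcor` and `sign` (+1 positive association, -1 negative), strongest
#'   first.
#' @export
top_edges <- function(fit, quantile_frac = 0.03, method = c("omega", "pcor")) {
  method <- match.arg(method)
  if (quantile_frac <= 0 || quantile_frac >= 1)
    stop("quantile_frac must be in (0, 1)")
  arr <- if (inherits(fit, "mgcgm")) fit$draws$Omega else fit
  M <- apply(arr, c(2, 3), mean)
  nm <- if (inherits(fit, "mgcgm")) colnames(fit$data$values)
        else paste0("V", seq_len(ncol(M)))
  pc <- partial_correlation(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  score <- if (method == "omega") abs(M[ut]) else abs(pc[ut])
  keep <- floor(quantile_frac * nrow(ut))
  ord <- order(score, decreasing = TRUE)
  ord <- ord[seq_len(min(keep, nrow(ut)))]
  ord <- ord[score[ord] > 0]
  if (!length(ord)) {
    warning("all candidate edges have zero posterior mean; empty edge list")
    ord <- integer(0)
  }
  data.frame(from = nm[ut[ord, 1]], to = nm[ut[ord, 2]],
             weight = M[ut][ord], pcor = pc[ut][ord],
             sign = ifelse(pc[ut][ord] >= 0, 1L, -1L))
}

.edges_to_igraph <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  igraph::E(g)$weight <- abs(edges$weight)
  igraph::E(g)$sign <- edges$sign
  igraph::E(g)$pcor <- edges$pcor
  g
}

#' Export an edge list to GraphML
#'
#' @param edges data.frame from [top_edges()].
#' @param path output `.graphml` file.
#' @export
write_edges_graphml <- function(edges, path) {
  igraph::write_graph(.edges_to_igraph(edges), path, format = "graphml")
  invisible(path)
}

#' Conditional associations with a chosen response
#'
#' Applies [conditional_coefficients()] to every saved draw of the latent
#' covariance and summarizes each predictor's coefficient by its posterior
#' mean, 95% HDR and a flag for intervals excluding 0.  Numerically singular
#' draws are skipped with a warning and counted.
#'
#' @param fit an `mgcgm` fit, or a K x p x p array of covariance draws.
#' @param response response column name or index.
#' @param mass HDR mass (default 0.95).
#' @return data.frame with `predictor`, `mean`, `lo`, `hi`, `flag`; the
#'   number of skipped draws is attached as attribute `"n_skipped"`.
#' @export
association_report <- function(fit, response, mass = 0.95) {
  arr <- if (inherits(fit, "mgcgm")) fit$draws$Gamma else fit
  nm <- if (inherits(fit, "mgcgm")) colnames(fit$data$values)
        else paste0("V", seq_len(dim(arr)[2]))
  l <- if (is.character(response)) match(response, nm) else as.integer(response)
  if (is.na(l) || l < 1 || l > dim(arr)[2]) stop("response not found")
  K <- dim(arr)[1]
  cf <- matrix(NA_real_, K, dim(arr)[2] - 1)
  skipped <- 0L
  for (k in seq_len(K)) {
    cf[k, ] <- tryCatch(conditional_coefficients(arr[k, , ], l),
                        error = function(e) { skipped <<- skipped + 1L
                                              rep(NA_real_, ncol(cf)) })
  }
  if (skipped > 0)
    warning(sprintf("%d singular draws skipped", skipped))
  ok <- complete.cases(cf)
  out <- data.frame(predictor = nm[-l], mean = colMeans(cf[ok, , drop = FALSE]),
                    lo = NA_real_, hi = NA_real_, flag = FALSE)
  for (j in seq_len(ncol(cf))) {
    h <- hdr(cf[ok, j], mass)
    out$lo[j] <- h[1]; out$hi[j] <- h[2]
    out$flag[j] <- h[1] > 0 || h[2] < 0
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Posterior-predictive risk scores for a rare binary outcome
#'
#' For each of `reps` uniformly resampled saved draws s: every person's
#' latent outcome coordinate is redrawn from its conditional normal given the
#' person's other latent coordinates and cluster effect, *without*
#' truncation (the outcome is treated as missing); the draw is scored 1 when
#' it exceeds that draw's benchmark, the smallest stored latent value among
#' the observed positive cases.  The score is the mean indicator over
#' repetitions, a number in \[0, 1\] per person.
#'
#' @param fit an `mgcgm` fit run with `store_z = TRUE`.
#' @param outcome binary outcome column name or index with at least one
#'   observed positive case.
#' @param reps number of posterior-predictive repetitions (default 500).
#' @return numeric vector of per-person scores in \[0, 1\].
#' @export
predictive_score <- function(fit, outcome, reps = 500) {
  if (is.null(fit$draws$Z))
    stop("fit must be run with store_z = TRUE for predictive scoring")
  nm <- colnames(fit$data$values)
  e <- if (is.character(outcome)) match(outcome, nm) else as.integer(outcome)
  if (is.na(e)) stop("outcome column not found")
  if (fit$data$types[e] != "binary") stop("outcome must be a binary column")
  y <- fit$data$values[, e]
  pos <- which(!is.na(y) & y == 1)
  if (!length(pos)) stop("outcome has no observed positive cases")
  K <- dim(fit$draws$Omega)[1]
  N <- nrow(fit$data$values)
  cl <- fit$data$cluster
  hits <- numeric(N)
  idx <- sample.int(K, reps, replace = TRUE)
  for (s in idx) {
    Om <- fit$draws$Omega[s, , ]
    w <- -Om[e, -e] / Om[e, e]
    sdv <- sqrt(1 / Om[e, e])
    Zs <- matrix(fit$draws$Z[s, , ], N)
    Bs <- matrix(fit$draws$B[s, , ], dim(fit$draws$B)[2])
    mu <- Bs[cl, e] + (Zs[, -e, drop = FALSE] -
                         Bs[cl, -e, drop = FALSE]) %*% w
    zstar <- rnorm(N, mu, sdv)
    benchmark <- min(Zs[pos, e])
    hits <- hits + (zstar > benchmark)
  }
  hits / reps
}

#' Frequentist coverage study of the calibration design
#'
#' Repeatedly simulates the built-in four-variable multilevel design
#' ([simulate_calibration_data()]), fits the model at each shrinkage setting
#' `t`, computes the 95% HDR of every unique precision and random-effect
#' covariance entry, and reports the fraction of replicates whose HDR
#' contains the generating truth.  HDRs are computed on the stored
#' (identified-scale) `Omega`/`Psi` draws, the scale the truth matrices live
#' on.
#'
#' @param t_values shrinkage hyper-parameter settings (default
#'   `c(1e-1, 1e-3, 1e-5)`).
#' @param replicates number of replicate datasets per setting.
#' @param s shape hyper-parameter (default 0.01).
#' @param n_iter,thin,burn_frac chain settings per replicate; the defaults
#'   (20000 / 10 / 0.5) are the reference sampler settings.
#' @param mass HDR mass (default 0.95).
#' @param seed integer seed; replicate r at setting i uses derived seeds.
#' @param latent `"observed"` (default) fixes the latent matrix at the
#'   generated Gaussian columns; `"rank"` uses the extended-rank-likelihood
#'   sweep.
#' @param verbose print progress.
#' @return data.frame in long layout: `matrix` ("Omega"/"Psi"), `i`, `j`,
#'   `parameter`, `true`, `t`, `coverage` (percent).
#' @export
coverage_study <- function(t_values = c(1e-1, 1e-3, 1e-5), replicates = 50,
                           s = 0.01, n_iter = 20000, thin = 10,
                           burn_frac = 0.5, mass = 0.95, seed = 1,
                           latent = c("observed", "rank"), verbose = FALSE) {
  latent <- match.arg(latent)
  if (replicates < 10) stop("use at least 10 replicates")
  tr <- calibration_truth()
  ut <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  res <- NULL
  for (ti in seq_along(t_values)) {
    hit_om <- hit_ps <- matrix(0, replicates, nrow(ut))
    for (r in seq_len(replicates)) {
      rep_seed <- (seed + 1543L * (ti - 1L) + 7919L * r) %% 2147483629L
      set.seed(rep_seed)
      dat <- simulate_calibration_data()
      fit <- mgcgm(dat, s = s, t = t_values[ti], n_iter = n_iter,
                   thin = thin, burn_frac = burn_frac, n_chains = 1,
                   seed = rep_seed + 1L, latent_update = latent == "rank")
      for (k in seq_len(nrow(ut))) {
        i <- ut[k, 1]; j <- ut[k, 2]
        h <- hdr(fit$draws$Omega[, i, j], mass)
        hit_om[r, k] <- h[1] <= tr$Omega[i, j] && tr$Omega[i, j] <= h[2]
        h <- hdr(fit$draws$Psi[, i, j], mass)
        hit_ps[r, k] <- h[1] <= tr$Psi[i, j] && tr$Psi[i, j] <= h[2]
      }
      if (verbose)
        message(sprintf("t = %g: replicate %d/%d", t_values[ti], r, replicates))
    }
    res <- rbind(res,
      data.frame(matrix = "Omega", i = ut[, 1], j = ut[, 2],
                 parameter = sprintf("omega_%d%d", ut[, 1], ut[, 2]),
                 true = tr$Omega[ut], t = t_values[ti],
                 coverage = 100 * colMeans(hit_om)),
      data.frame(matrix = "Psi", i = ut[, 1], j = ut[, 2],
                 parameter = sprintf("psi_%d%d", ut[, 1], ut[, 2]),
                 true = tr$Psi[ut], t = t_values[ti],
                 coverage = 100 * colMeans(hit_ps)))
  }
  rownames(res) <- NULL
  res
}
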