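test_that("hdr matches analytic intervals", {
  set.seed(81)
  u <- runif(1e5)
  h <- hdr(u, 0.95)
  expect_lt(abs(diff(h) - 0.95), 0.01)

  z <- rnorm(1e5)
  h <- hdr(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)

  h <- hdr(rep(3, 100))
  expect_equal(h, c(3, 3))
  expect_error(hdr(rnorm(10)), "too few")
  # contains the median of unimodal draws
  x <- rgamma(5000, 2, 1)
  h <- hdr(x)
  expect_true(h[1] < median(x) && median(x) < h[2])
})

test_that("cohort contrasts difference the cohort means of cluster effects", {
  # 4 + 3 clusters in two cohorts, p = 2, constructed draws
  dat <- mixed_data(matrix(rnorm(14), 7, 2), "continuous", 1:7,
                    cohort_of_cluster = setNames(c(rep("a", 4), rep("b", 3)),
                                                 as.character(1:7)))
  K <- 200
  B <- array(0, c(K, 7, 2))
  fit <- structure(list(draws = list(B = B), data = dat), class = "mgcgm")
  cc <- cohort_contrast(fit)
  expect_equal(cc$mean, c(0, 0))
  expect_false(any(cc$flag))

  B[, 1:4, 1] <- 1                           # cohort a shifted in variable 1
  B <- B + array(rnorm(length(B), sd = 1e-3), dim(B))
  fit$draws$B <- B
  cc <- cohort_contrast(fit)
  expect_equal(cc$mean[1], 1, tolerance = 0.01)
  expect_true(cc$flag[1])
  expect_false(cc$flag[2])
})

test_that("cohort shifts injected into the generator are recovered", {
  set.seed(82)
  delta <- 0.8
  tr <- list(Omega = diag(3), Psi = 0.05 * diag(3))
  sim <- simulate_latent(8, 40, tr$Omega, tr$Psi)
  shift <- ifelse(sim$cluster <= 4, delta / 2, -delta / 2)
  Z <- sim$Z
  Z[, 1] <- Z[, 1] + shift
  co <- setNames(c(rep("c1", 4), rep("c2", 4)), as.character(1:8))
  dat <- mixed_data(Z, "continuous", sim$cluster, cohort_of_cluster = co)
  fit <- mgcgm(dat, n_iter = 600, thin = 5, burn_frac = 0.5, seed = 83)
  cc <- cohort_contrast(fit)
  d_sd <- (cc$hi[1] - cc$lo[1]) / 4
  expect_lt(abs(cc$mean[1] - delta), 3 * d_sd + 0.2)
  expect_true(cc$flag[1])
})

test_that("edge selection keeps the strongest upper-triangular entries", {
  # p = 105 gives 5460 candidate pairs; 3% keeps 163
  p <- 105
  set.seed(84)
  M <- matrix(0, p, p)
  M[upper.tri(M)] <- rnorm(p * (p - 1) / 2)
  M <- M + t(M); diag(M) <- p
  arr <- array(M, c(1, p, p))
  ed <- top_edges(arr, 0.03)
  expect_equal(nrow(ed), 163)
  expect_equal(nrow(ed), floor(0.03 * choose(105, 2)))
  # selected magnitudes dominate the unselected ones
  thresh <- min(abs(ed$weight))
  allmag <- abs(M[upper.tri(M)])
  expect_equal(sum(allmag >= thresh), 163)

  # diagonal draws: no edges at any fraction below one
  diag_arr <- array(0, c(5, 4, 4))
  for (k in 1:5) diag_arr[k, , ] <- diag(4)
  expect_warning(ed0 <- top_edges(diag_arr, 0.5), "zero posterior mean")
  expect_equal(nrow(ed0), 0)
})

test_that("true edges of a sparse precision outrank true non-edges", {
  set.seed(85)
  Om <- diag(6)
  Om[1, 2] <- Om[2, 1] <- -0.45
  Om[3, 4] <- Om[4, 3] <- 0.4
  sim <- simulate_latent(6, 60, Om, 0.1 * diag(6))
  dat <- mixed_data(sim$Z, "continuous", sim$cluster)
  fit <- mgcgm(dat, n_iter = 500, thin = 5, burn_frac = 0.5, seed = 86)
  M <- abs(apply(fit$draws$Omega, c(2, 3), mean))
  truthy <- c(M[1, 2], M[3, 4])
  falsy <- M[upper.tri(M)][!(abs(Om[upper.tri(Om)]) > 0)]
  expect_gt(min(truthy), median(falsy))
  ed <- top_edges(fit, 0.14)               # 2 of 15 pairs
  expect_setequal(paste(ed$from, ed$to), c("V1 V2", "V3 V4"))
  expect_equal(ed$sign[ed$from == "V1"], 1)  # negative omega = positive assoc
  expect_equal(ed$sign[ed$from == "V3"], -1)
})

test_that("graphml export writes a readable graph", {
  ed <- data.frame(from = c("a", "b"), to = c("b", "c"),
                   weight = c(-0.5, 0.2), pcor = c(0.5, -0.2),
                   sign = c(1L, -1L))
  path <- tempfile(fileext = ".graphml")
  write_edges_graphml(ed, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
  expect_equal(sort(igraph::V(g)$name), c("a", "b", "c"))
  unlink(path)
})

test_that("association reports summarize per-draw conditional coefficients", {
  K <- 120
  arr <- array(0, c(K, 3, 3))
  for (k in 1:K) arr[k, , ] <- diag(3)
  rep0 <- association_report(arr, 1)
  expect_equal(rep0$mean, c(0, 0))
  expect_false(any(rep0$flag))

  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  arr2 <- array(0, c(K, 2, 2))
  for (k in 1:K) arr2[k, , ] <- G
  rep1 <- association_report(arr2, 1)
  expect_equal(rep1$mean, 0.5)
  expect_true(rep1$flag)
})

test_that("a known conditional coefficient is recovered on synthetic data", {
  set.seed(87)
  Om <- diag(4); Om[1, 2] <- Om[2, 1] <- -0.5
  sim <- simulate_latent(5, 80, Om, 0.05 * diag(4))
  dat <- mixed_data(sim$Z, "continuous", sim$cluster)
  fit <- mgcgm(dat, n_iter = 500, thin = 5, burn_frac = 0.5, seed = 88)
  rep1 <- association_report(fit, 1)
  # true coefficient of V2 on V1 is -Om[1,2]/Om[1,1] = 0.5
  row <- rep1[rep1$predictor == "V2", ]
  post_sd <- (row$hi - row$lo) / 4
  expect_lt(abs(row$mean - 0.5), 3.5 * post_sd)
  expect_true(row$flag)
})

test_that("predictive scores are probabilities and saturate for clear cases", {
  set.seed(89)
  dat <- make_mixed_toy(n_per = 25, m = 3, p = 3)
  fit <- mgcgm(dat, n_iter = 200, thin = 5, burn_frac = 0.5, seed = 90,
               store_z = TRUE)
  sc <- predictive_score(fit, 3, reps = 100)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predictive_score(fit, 1), "binary")

  # hand-built fit: person 1's conditional mean sits 20 sd above every
  # stored benchmark, so the predictive indicator is always 1
  K <- 60; N <- 5
  Om <- matrix(c(1, -0.9, -0.9, 1), 2, 2) * 5
  y <- cbind(rnorm(N), c(0, 1, 0, 0, 0))
  d2 <- mixed_data(y, c("continuous", "binary"), rep(1, N))
  Z <- cbind(c(10, 0.5, -1, 0, 1), c(0, 0.4, -1, -0.2, 0.1))
  draws <- list(Omega = array(NA_real_, c(K, 2, 2)),
                Z = array(NA_real_, c(K, N, 2)),
                B = array(0, c(K, 1, 2)))
  for (k in 1:K) { draws$Omega[k, , ] <- Om; draws$Z[k, , ] <- Z }
  fit2 <- structure(list(draws = draws, data = d2), class = "mgcgm")
  sc2 <- predictive_score(fit2, 2, reps = 100)
  expect_equal(sc2[1], 1)       # mean 0.9 * 10 = 9, sd sqrt(1/5), benchmark 0.4
  expect_lt(sc2[3], 0.05)
})

test_that("predictive scores ignore relabeling of non-outcome columns", {
  set.seed(91)
  dat <- make_mixed_toy(n_per = 25, m = 3, p = 3)
  fit <- mgcgm(dat, n_iter = 200, thin = 5, burn_frac = 0.5, seed = 92,
               store_z = TRUE)
  perm <- c(2, 1, 3)
  fit_p <- fit
  fit_p$data$values <- fit$data$values[, perm]
  fit_p$data$types <- fit$data$types[perm]
  colnames(fit_p$data$values) <- colnames(fit$data$values)[perm]
  fit_p$draws$Gamma <- fit$draws$Gamma[, perm, perm, drop = FALSE]
  fit_p$draws$Omega <- fit$draws$Omega[, perm, perm, drop = FALSE]
  fit_p$draws$Psi <- fit$draws$Psi[, perm, perm, drop = FALSE]
  fit_p$draws$B <- fit$draws$B[, , perm, drop = FALSE]
  fit_p$draws$Z <- fit$draws$Z[, , perm, drop = FALSE]
  set.seed(1); s1 <- predictive_score(fit, 3, reps = 50)
  set.seed(1); s2 <- predictive_score(fit_p, "V3", reps = 50)
  expect_equal(s1, s2)
})

test_that("summary, coef, plot and simulate methods work together", {
  set.seed(93)
  dat <- make_mixed_toy(n_per = 20, m = 3, p = 3)
  fit <- mgcgm(dat, n_iter = 400, thin = 2, burn_frac = 0.5, seed = 94)
  s <- summary(fit)
  expect_equal(unname(s$total_variance), rep(1, 3), tolerance = 1e-9)
  expect_equal(coef(fit), s$omega_mean)
  cf <- coef(fit, response = "V1")
  expect_named(cf, c("V2", "V3"))

  path <- tempfile(fileext = ".png")
  grDevices::png(path)
  plot(fit, type = "trace")
  grDevices::dev.off()
  expect_true(file.exists(path))
  unlink(path)

  reps <- simulate(fit, nsim = 2, seed = 95)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "mixed_data")
  expect_identical(dim(reps[[1]]$values), dim(dat$values))
  expect_identical(reps[[1]]$types, dat$types)
})
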