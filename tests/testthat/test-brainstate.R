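test_that("standardization is an idempotent per-column z-score", {
  expect_equal(drop(standardize_ts(matrix(1:3))), c(-1, 0, 1))
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  Z <- standardize_ts(X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  expect_equal(standardize_ts(Z), Z, tolerance = 1e-12)
  Xc <- X; Xc[, 2] <- 7; colnames(Xc) <- paste0("p", 1:4)
  expect_error(standardize_ts(Xc), "p2")
})

test_that("PCA keeps the smallest component count reaching the variance threshold", {
  # rank-1 data
  set.seed(8)
  u <- rnorm(100); v <- rnorm(5)
  X1 <- outer(u, v)
  p1 <- pca_fit(X1, 0.9)
  expect_equal(p1$D, 1L)
  expect_equal(p1$explained_ratio[1], 1, tolerance = 1e-10)

  # isotropic data: the spectrum is flat, so ~threshold * P components
  Xi <- matrix(rnorm(10000 * 20), 10000, 20)
  pi <- pca_fit(Xi, 0.9)
  # oracle: directly from the eigenvalues of the sample covariance
  ev <- sort(eigen(stats::cov(Xi), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  D_oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(pi$D, D_oracle)
  expect_true(abs(pi$D - 18) <= 1)

  # full-rank projection reconstructs rank-D data
  Xr <- matrix(rnorm(300 * 3), 300, 3) %*% matrix(rnorm(12), 3, 4)
  pr <- pca_fit(Xr, 1 - 1e-9)
  back <- pca_backproject(pr, pca_project(pr, Xr))
  expect_equal(back, Xr, tolerance = 1e-8)
  expect_error(pca_fit(Xr, 1.2), "0, 1")

  # threshold invariant: cumulative at D >= thr, at D-1 < thr
  cum <- cumsum(pi$explained_ratio)
  expect_gte(cum[pi$D], 0.9 - 1e-12)
  expect_lt(cum[pi$D - 1], 0.9)
})

test_that("forward log-likelihood and posteriors match path enumeration", {
  set.seed(17)
  for (case in list(c(T = 6, K = 2, D = 2), c(T = 8, K = 3, D = 1),
                    c(T = 5, K = 3, D = 2))) {
    T <- case["T"]; K <- case["K"]; D <- case["D"]
    A <- matrix(runif(K * K), K); A <- A / rowSums(A)
    init <- runif(K); init <- init / sum(init)
    means <- matrix(rnorm(K * D, sd = 2), K, D)
    covs <- replicate(K, {
      M <- matrix(rnorm(D * D), D); crossprod(M) / D + diag(0.5, D)
    }, simplify = FALSE)
    Y <- matrix(rnorm(T * D), T, D)
    model <- list(initial = init, transitions = A, means = means,
                  covariances = covs)
    dec <- hmm_decode(model, Y)
    oracle <- enum_hmm(Y, init, A, means, covs)
    expect_equal(dec$loglik, oracle$loglik, tolerance = 1e-8)
    expect_equal(dec$gamma, oracle$gamma, tolerance = 1e-8)
  }
})

test_that("EM recovers a well-separated 2-state model and is monotone", {
  set.seed(23)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  path <- integer(2000); path[1] <- 1
  for (t in 2:2000) path[t] <- sample(1:2, 1, prob = A[path[t - 1], ])
  mu <- rbind(c(-3, 0), c(3, 0))   # separation 6 sigma
  Y <- mu[path, ] + matrix(rnorm(4000), 2000, 2)
  fit <- hmm_fit(Y, K = 2, seed = 1, n_restarts = 2, max_iter = 100)
  # objective nondecreasing to numerical slack
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik_trace[-1])))
  dec <- hmm_decode(fit, Y)
  acc <- max(mean(dec$viterbi == path), mean(3 - dec$viterbi == path))
  expect_gte(acc, 0.95)
  expect_equal(rowSums(fit$transitions), c(1, 1), tolerance = 1e-10)
  # gamma rows live on the simplex
  expect_true(all(abs(rowSums(dec$gamma) - 1) < 1e-10))
  # posterior argmax and Viterbi agree on nearly all frames here
  expect_gte(mean(max.col(dec$gamma) == dec$viterbi), 0.9)
})

test_that("a 1-state fit degenerates to the maximum-likelihood Gaussian", {
  set.seed(4)
  Y <- matrix(rnorm(600), 200, 3)
  fit <- hmm_fit(Y, K = 1, seed = 1, n_restarts = 1)
  mu <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, mu)) / 200 + diag(1e-8, 3)
  ch <- chol(S)
  Q <- sweep(Y, 2, mu) %*% backsolve(ch, diag(3))
  ll <- sum(-0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(Q^2)))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("noiseless emissions decode to the generating path exactly", {
  set.seed(6)
  means <- rbind(c(0, 0), c(4, 0), c(0, 4))
  path <- sample(1:3, 60, replace = TRUE)
  Y <- means[path, ] + matrix(rnorm(120, sd = 1e-4), 60, 2)
  model <- list(initial = rep(1 / 3, 3),
                transitions = matrix(1 / 3, 3, 3),
                means = means, covariances = replicate(3, diag(2), simplify = FALSE))
  dec <- hmm_decode(model, Y)
  expect_identical(dec$viterbi, path)
})

test_that("multi-sequence fitting respects chain boundaries", {
  # two sequences that each start in a different state: the initial
  # distribution must reflect both starts, which only happens if the
  # recursion restarts at the boundary
  set.seed(9)
  mk <- function(s0) {
    path <- c(rep(s0, 50), rep(3 - s0, 50))
    rbind(c(-3, 0), c(3, 0))[path, ] + matrix(rnorm(200, sd = 0.3), 100, 2)
  }
  fit <- hmm_fit(list(mk(1), mk(2)), K = 2, seed = 2, n_restarts = 2)
  expect_equal(sort(fit$initial), c(0.5, 0.5), tolerance = 0.05)
})

test_that("fractional occupancy counts hard assignments on the simplex", {
  expect_equal(fractional_occupancy(c(1, 1, 2, 3, 2), K = 3), c(0.4, 0.4, 0.2))
  expect_equal(fractional_occupancy(c(1, 1, 2), interval = 2, K = 2), c(1, 0))
  expect_error(fractional_occupancy(c(1, 2), interval = integer(0), K = 2), "empty")
  # whole-run FO equals the coverage-weighted mean of disjoint window FOs
  set.seed(12)
  path <- sample(1:4, 90, replace = TRUE)
  whole <- fractional_occupancy(path, K = 4)
  parts <- sapply(seq(1, 90, by = 30), function(s) {
    fractional_occupancy(path, interval = s:(s + 29), K = 4)
  })
  expect_equal(rowMeans(parts), whole, tolerance = 1e-12)
  expect_equal(sum(whole), 1)
})

test_that("state profiles recover planted activation blocks and clean FC nulls", {
  cfg <- synth_config(n_subjects = 8, n_raters = 4, T_per_run = c(300, 300),
                      P = 60, K_true = 4, seed = 15)
  co <- gen_cohort(cfg)
  X_list <- unlist(lapply(co$parcel_series, function(r) lapply(r, standardize_ts)),
                   recursive = FALSE)
  paths <- unlist(lapply(co$subject_paths, identity), recursive = FALSE)
  subject <- rep(seq_len(8), each = 2)
  prof <- state_profiles(X_list, paths, K = 4, subject = subject,
                         networks = co$true_model$networks$network_17)
  for (k in 1:4) {
    occ <- rep(1 / 4, 4)
    mu <- co$true_model$means
    mbar <- colSums(mu * occ)
    s_tot <- sqrt(colSums(sweep(mu, 2, mbar)^2 * occ) + cfg$emission_sigma^2)
    planted <- (mu[k, ] - mbar) / s_tot
    expect_gte(cor(prof[[k]]$activation_map, planted), 0.95)
    expect_equal(diag(prof[[k]]$fc), rep(1, 60))
    expect_false(prof[[k]]$empty)
  }
  # all states share one (identity) covariance: FC contrasts should be quiet
  frac_sig <- mean(vapply(prof, function(p) mean(p$contrast$sig), numeric(1)))
  expect_lt(frac_sig, 0.05)
})
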