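test_that("confound residualization is train-fitted OLS with exact orthogonality", {
  set.seed(61)
  n <- 80
  conf <- data.frame(age = rnorm(n), motion = abs(rnorm(n)))
  X <- matrix(rnorm(n * 3), n, 3)
  rc <- residualize_confounds(X, conf)
  for (j in 1:3) {
    expect_lt(abs(cor(rc$train[, j], conf$age)), 1e-10)
    expect_lt(abs(cor(rc$train[, j], conf$motion)), 1e-10)
  }
  # a feature that IS a confound residualizes to ~0
  X2 <- cbind(2 * conf$age, X[, 1])
  rc2 <- residualize_confounds(X2, conf)
  expect_lt(max(abs(rc2$train[, 1])), 1e-10)
  # a confound orthogonal to the feature leaves it unchanged
  f <- rnorm(n)
  ortho <- drop(qr.resid(qr(cbind(1, f)), rnorm(n)))
  rc3 <- residualize_confounds(matrix(f), data.frame(c1 = ortho))
  expect_equal(drop(rc3$train), f - mean(f), tolerance = 1e-10)
  # constant confounds (e.g. single-sex cohorts) are dropped with a warning
  expect_warning(residualize_confounds(X, data.frame(sex = rep(1, n))), "constant")
})

test_that("min-max scaling uses training parameters without clipping", {
  sc <- minmax_scale(matrix(c(2, 4, 6)), matrix(8))
  expect_equal(drop(sc$train), c(0, 0.5, 1))
  expect_equal(drop(sc$test), 1.5)
  # idempotent only once the data are already in [0, 1]
  sc2 <- minmax_scale(sc$train)
  expect_equal(sc2$train, sc$train)
  expect_warning(minmax_scale(matrix(rep(3, 4))), "zero-range")
})

test_that("ridge matches the closed-form normal equations", {
  m <- ridge_fit(matrix(c(1, 2)), c(1, 2), 0)
  expect_equal(unname(m$weights), 1, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  m2 <- ridge_fit(matrix(c(1, -1)), c(1, -1), 1)
  expect_equal(unname(m2$weights), 2 / 3, tolerance = 1e-12)
  # shrinkage limit
  set.seed(1)
  yv <- rnorm(20) + 5
  m3 <- ridge_fit(matrix(rnorm(20)), yv, 1e9)
  expect_lt(abs(m3$weights), 1e-6)
  expect_equal(m3$intercept, mean(yv), tolerance = 1e-4)
  # random small systems against a direct solve oracle
  set.seed(62)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 20, 3); y <- rnorm(20); lam <- runif(1, 0.1, 5)
    m <- ridge_fit(X, y, lam)
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    w_oracle <- solve(crossprod(Xc) + diag(lam, 3), crossprod(Xc, yc))
    expect_equal(unname(m$weights), drop(w_oracle), tolerance = 1e-8)
  }
  # collinear features at lambda = 0 fail loudly
  Xs <- cbind(1:10, (1:10) * 2)
  expect_error(ridge_fit(Xs, rnorm(10), 0), "lambda > 0")
})

test_that("penalty selection prefers dominating candidates and breaks ties low", {
  set.seed(63)
  ds <- make_planted_dataset(n_subjects = 10, W = 60, seed = 63)
  rows <- statecue:::dataset_rows(ds, ds$covariates$subject_id,
                                  c("age", "sex", "motion"))
  sel <- select_lambda(rows$X, rows$y, rows$subjects, grid = lambda_grid(8),
                       inner_folds = 5, seed = 1)
  expect_true(sel$lambda %in% lambda_grid(8))
  tab <- sel$table
  # chosen lambda minimizes the distance, first occurrence wins
  expect_equal(sel$lambda, tab$lambda[which(tab$distance == min(tab$distance))[1]])
  # collinear features push the selected penalty above zero
  hits <- 0
  for (s in 1:10) {
    dsc <- make_planted_dataset(n_subjects = 8, W = 50, K = 4,
                                w_true = c(1, -1, 0.5, 0), subj_noise = 0.02,
                                seed = 100 + s)
    for (i in seq_along(dsc$FO_by_subject)) {
      dsc$FO_by_subject[[i]][, 4] <- dsc$FO_by_subject[[i]][, 1] * 0.98 +
        rnorm(50, 0, 0.01)
    }
    rows <- statecue:::dataset_rows(dsc, dsc$covariates$subject_id, "age")
    sel <- select_lambda(rows$X, rows$y, rows$subjects, grid = lambda_grid(10),
                         inner_folds = 4, seed = s)
    if (sel$lambda > min(lambda_grid(10))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("LOSO recovers planted weights and no information leaks from test rows", {
  ds <- make_planted_dataset(seed = 64)
  cv <- loso_cv(ds, grid = lambda_grid(8), seed = 1)
  expect_gte(cv$individual_mean_r, 0.5)
  expect_length(cv$per_subject_r, 20)
  expect_gt(cv$group_r, 0.5)
  # leakage probe: perturbing test rows leaves train-fitted parameters alone
  set.seed(65)
  tr_X <- matrix(rnorm(200), 50, 4)
  tr_C <- data.frame(age = rnorm(50))
  te_X <- matrix(rnorm(40), 10, 4)
  te_C <- data.frame(age = rnorm(10))
  rc1 <- residualize_confounds(tr_X, tr_C, te_X, te_C)
  rc2 <- residualize_confounds(tr_X, tr_C, te_X + 100, te_C)
  expect_identical(rc1$coef, rc2$coef)
  expect_identical(rc1$train, rc2$train)
  sc1 <- minmax_scale(tr_X, te_X)
  sc2 <- minmax_scale(tr_X, te_X * 50)
  expect_identical(sc1$min, sc2$min)
  expect_identical(sc1$max, sc2$max)
  expect_identical(sc1$train, sc2$train)
  # a subject present in train and test predicts near-perfectly (sanity probe
  # that the harness can detect leakage when it is deliberately introduced)
  leak <- cross_generalize(ds, ds, cv$group_lambda)
  expect_gt(leak$individual_mean_r, cv$individual_mean_r - 0.05)
})

test_that("cross-dataset generalization works between cohorts sharing the mapping", {
  dsA <- make_planted_dataset(seed = 66)
  dsB <- make_planted_dataset(seed = 67)
  res <- cross_generalize(dsA, dsB, lambda = 1)
  expect_gte(res$individual_mean_r, 0.5)
  # decoupled target: no generalization
  dsC <- make_planted_dataset(seed = 68)
  for (i in seq_along(dsC$FO_by_subject)) {
    dsC$FO_by_subject[[i]] <- matrix(runif(180 * 6), 180, 6,
                                     dimnames = list(NULL, paste0("state_", 1:6)))
  }
  res0 <- cross_generalize(dsA, dsC, lambda = 1)
  expect_lt(abs(res0$individual_mean_r), 0.15)
  dsD <- make_planted_dataset(K = 3, w_true = c(1, 0, -1), seed = 69)
  expect_error(cross_generalize(dsA, dsD, 1), "feature counts")
})

test_that("bootstrap importance flags planted weights with the right signs", {
  ds <- make_planted_dataset(n_subjects = 15, W = 120, seed = 70)
  imp <- bootstrap_importance(ds, lambda = 1, B = 300, seed = 1)
  expect_gt(imp$z[1], 0)       # planted +1
  expect_lt(imp$z[2], 0)       # planted -0.8
  expect_true(all(imp$sig[1:2]))
  # the null feature is by far the least stable contributor; its Z can still
  # be nonzero because the stimulus-locked spurious fit is fixed across
  # subject resamples (see the methods vignette)
  expect_lt(abs(imp$z[5]), min(abs(imp$z[1:2])))
  expect_error(bootstrap_importance(ds, 1, B = 1), "undefined")
})

test_that("BH step-up flags follow the textbook rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # flags are monotone in p
  p <- sort(runif(20))
  flags <- bh_fdr(p, 0.2)
  expect_true(all(diff(as.integer(flags)) <= 0))
})
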