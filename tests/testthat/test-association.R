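test_that("state expression is the windowed FO-target correlation", {
  set.seed(71)
  target <- rnorm(200)
  expect_equal(state_expression(target, target), 1)
  # affine rescaling of the target does not change expression
  fo <- runif(200)
  expect_equal(state_expression(fo, target),
               state_expression(fo, 3 * target + 7), tolerance = 1e-12)
  # independent FO: correlation near zero
  expect_lt(abs(state_expression(runif(500), rnorm(500))), 0.15)
  expect_warning(e <- state_expression(rep(0.5, 50), rnorm(50)), "constant")
  expect_true(is.na(e))
  expect_error(state_expression(runif(5), rnorm(5)), "at least 10")
})

test_that("estimated expression tracks the planted coupling gain", {
  cfg <- synth_config(n_subjects = 50, n_raters = 6, T_per_run = c(1500, 1500),
                      seed = 72)
  co <- gen_cohort(cfg, brain = FALSE)
  # windowed FO of the top-weight state per subject, group appetite target
  kern <- hrf_kernel()
  schemes <- lapply(cfg$T_per_run, make_windows)
  target <- unlist(lapply(1:2, function(r) {
    windowed_features(co$group_path[[r]],
                      hrf_convolve(co$appetite_truth[[r]], kern),
                      schemes[[r]], K = 6)$target
  }))
  expr <- vapply(seq_len(50), function(i) {
    fo <- unlist(lapply(1:2, function(r) {
      windowed_features(co$subject_paths[[i]][[r]], co$appetite_truth[[r]],
                        schemes[[r]], K = 6)$FO[, 6]
    }))
    cor(fo, target)
  }, numeric(1))
  expect_gte(cor(expr, co$covariates$coupling_gain), 0.5)
})

test_that("group comparison matches the textbook pooled t", {
  res <- group_compare(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  # identical groups: t = 0, p = 1
  res0 <- group_compare(rep(c(1, 2), 4), rep(c("x", "y"), each = 4))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # clean separation
  set.seed(73)
  res1 <- group_compare(c(rnorm(4, 0, 1e-3), rnorm(4, 1, 1e-3)),
                        rep(c("lo", "hi"), each = 4))
  expect_lt(res1$p, 0.001)
  expect_error(group_compare(1:3, c("a", "a", "b")), "at least 2")
})

test_that("partial correlation removes shared covariate structure", {
  set.seed(74)
  x <- rnorm(50); y <- rnorm(50)
  plain <- partial_correlation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  # age drives both: raw r large, partial r near zero
  age <- rnorm(200)
  x2 <- age + rnorm(200, 0, 0.5)
  y2 <- age + rnorm(200, 0, 0.5)
  expect_gt(cor(x2, y2), 0.4)
  expect_lt(abs(partial_correlation(x2, y2, data.frame(age))$r), 0.2)
  # y identical to a covariate leaves a zero residual
  expect_warning(res <- partial_correlation(x2, age, data.frame(age)), "undefined")
  expect_true(is.na(res$r))
})

test_that("repeated-measures F matches the two-way decomposition by hand", {
  # printed 3x3 toy table, worked through the classical decomposition
  M <- rbind(c(1, 2, 3),
             c(2, 3, 5),
             c(0, 1, 2))
  n <- 3; C <- 3
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- C * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_hand <- (ss_cond / (C - 1)) / (ss_err / ((n - 1) * (C - 1)))
  res <- condition_fo_compare(M)
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_equal(res$df, c(2, 4))
  # identical conditions: F = 0
  res0 <- condition_fo_compare(matrix(rep(c(1, 2, 3), 3), 3, 3))
  expect_equal(res0$F, 0)
  expect_equal(nrow(res$pairwise), 3)
})

test_that("a planted condition shift is detected with high power", {
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    base <- matrix(rnorm(30 * 3, 0.3, 0.05), 30, 3)
    base[, 2] <- base[, 2] + 0.1
    if (condition_fo_compare(base)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("mediation paths satisfy a*b + c' = c and the exact chain", {
  set.seed(75)
  X <- rnorm(40)
  M <- X + rnorm(40, 0, 1e-3)   # deterministic chain, kept identifiable
  Y <- M                        # exact: b = 1, c' = 0 up to rounding
  res <- mediation_bca(X, M, Y, B = 200, seed = 1)
  expect_equal(res$a, 1, tolerance = 1e-2)
  expect_equal(res$b, 1, tolerance = 1e-8)
  expect_equal(res$c, res$a, tolerance = 1e-8)
  expect_equal(res$c_prime, 0, tolerance = 1e-8)
  expect_equal(res$indirect, res$a, tolerance = 1e-8)
  # identity holds exactly for arbitrary data with shared covariates
  X <- rnorm(60); M <- 0.4 * X + rnorm(60); Y <- 0.3 * M + 0.2 * X + rnorm(60)
  age <- rnorm(60)
  res2 <- mediation_bca(X, M, Y, covariates = data.frame(age), B = 100, seed = 2)
  expect_equal(res2$a * res2$b + res2$c_prime, res2$c, tolerance = 1e-10)
})

test_that("BCa reduces to the percentile interval for a symmetric bootstrap", {
  set.seed(76)
  # symmetric case: X standard normal, M and Y built so the indirect effect's
  # bootstrap distribution is symmetric around the estimate
  X <- rnorm(400)
  M <- 0.5 * X + rnorm(400)
  Y <- 0.5 * M + rnorm(400)
  res <- mediation_bca(X, M, Y, B = 2000, seed = 3)
  perc <- quantile(res$boot, c(0.025, 0.975))
  expect_lt(abs(res$ci_low - perc[1]), 0.02)
  expect_lt(abs(res$ci_high - perc[2]), 0.02)
  expect_true(res$significant)
})
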