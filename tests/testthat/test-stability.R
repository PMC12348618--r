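test_that("zRand matches a permutation null and is symmetric and relabel-invariant", {
  set.seed(41)
  a <- sample(1:3, 120, replace = TRUE)
  b <- ifelse(a == 1, sample(1:2, 120, replace = TRUE), a)  # related labelings
  z <- zrand(a, b)
  # permutation oracle: mean/sd of the pair-agreement statistic under shuffles
  w_obs <- rand_w(a, b)
  w_null <- replicate(4000, rand_w(a, sample(b)))
  z_perm <- (w_obs - mean(w_null)) / sd(w_null)
  expect_lt(abs(z - z_perm) / abs(z_perm), 0.1)
  expect_equal(zrand(a, b), zrand(b, a))
  # relabeling leaves the index unchanged
  b_relab <- c(9, 7, 8)[b]
  expect_equal(zrand(a, b_relab), z)
  # identical labelings score clearly positive
  expect_gt(zrand(rep(1:2, each = 3), rep(1:2, each = 3)), 0)
  expect_warning(z0 <- zrand(rep(1, 10), rep(1, 10)), "undefined")
  expect_true(is.nan(z0))
})

test_that("zRand is centred near zero for independent labelings", {
  set.seed(42)
  zs <- replicate(200, zrand(sample(1:4, 1000, replace = TRUE),
                             sample(1:4, 1000, replace = TRUE)))
  expect_gt(mean(zs), -0.2)
  expect_lt(mean(zs), 0.2)
})

test_that("NMI matches direct entropy computation and handles edge cases", {
  expect_equal(nmi(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(nmi(rep(1, 6), c(1, 2, 3, 1, 2, 3)), 0)
  # naive recomputation oracle on random instances
  set.seed(43)
  for (i in 1:5) {
    a <- sample(1:3, 8, replace = TRUE)
    b <- sample(1:2, 8, replace = TRUE)
    p <- table(a, b) / 8
    pa <- rowSums(p); pb <- colSums(p)
    H <- function(q) -sum(q[q > 0] * log(q[q > 0]))
    mi <- 0
    for (x in seq_along(pa)) for (y in seq_along(pb)) {
      if (p[x, y] > 0) mi <- mi + p[x, y] * log(p[x, y] / (pa[x] * pb[y]))
    }
    ref <- if (H(pa) == 0 || H(pb) == 0) 0 else mi / mean(c(H(pa), H(pb)))
    expect_equal(nmi(a, b), max(0, min(1, ref)), tolerance = 1e-12)
  }
})

test_that("ARI agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(44)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(ari(1:6, rep(c(1, 2), 3)), mclust::adjustedRandIndex(1:6, rep(c(1, 2), 3)))
})

test_that("state matching solves the assignment exactly", {
  set.seed(45)
  # row-permuted maps are recovered with concordance 1
  maps <- matrix(rnorm(5 * 30), 5, 30)
  perm <- sample(5)
  res <- match_states(maps, maps[perm, ])
  expect_equal(res$permutation, order(perm))
  expect_equal(res$concordance, 1, tolerance = 1e-10)
  # small noise keeps concordance high (SNR 10)
  noisy <- maps + matrix(rnorm(150, sd = sd(maps) / 10), 5, 30)
  expect_gte(match_states(maps, noisy)$concordance, 0.9)
  # exact agreement with K! enumeration on random similarity structures
  for (K in c(3, 4, 6)) {
    A <- matrix(rnorm(K * 25), K, 25)
    B <- matrix(rnorm(K * 25), K, 25)
    res <- match_states(A, B)
    oracle <- brute_match(suppressWarnings(cor(t(A), t(B))))
    expect_equal(sum(res$similarity[cbind(seq_len(K), res$permutation)]),
                 oracle$value, tolerance = 1e-10)
  }
})

test_that("the assignment solver matches brute force on arbitrary cost matrices", {
  set.seed(46)
  for (n in c(2, 4, 6)) {
    cost <- matrix(rnorm(n * n), n)
    sol <- statecue:::assignment_min(cost)
    perms <- all_perms(n)
    vals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
    expect_equal(sol$cost, min(vals), tolerance = 1e-12)
    expect_equal(sum(cost[cbind(seq_len(n), sol$assignment)]), min(vals),
                 tolerance = 1e-12)
  }
})

test_that("duplicated-subject split-halves give near-perfect stability", {
  cfg <- tiny_synth_config(seed = 18, T_per_run = c(120, 120))
  co <- gen_cohort(cfg)
  series1 <- lapply(co$parcel_series, function(r) lapply(r, standardize_ts))
  series <- c(series1, series1)  # each subject duplicated: halves can coincide
  st <- suppressWarnings(
    k_selection(series, K_range = 3, n_repeats = 3, seed = 1,
                n_restarts = 1, max_iter = 25, tol = 1e-3)
  )
  expect_gt(st$table$zrand_mean, 10)
  expect_gt(st$table$nmi_mean, 0.8)
})

test_that("time-shuffled data yields low, flat stability", {
  cfg <- tiny_synth_config(seed = 19, T_per_run = c(150, 150))
  co <- gen_cohort(cfg)
  set.seed(77)
  series <- lapply(co$parcel_series, function(runs) {
    lapply(runs, function(X) {
      # shuffle every parcel's samples independently: destroys the joint
      # state structure, leaving an unstructured cloud
      standardize_ts(apply(X, 2, sample))
    })
  })
  # shuffling time breaks the state structure entirely; compare NMI to the
  # structured version of the same cohort
  st_shuf <- suppressWarnings(
    k_selection(series, K_range = 3, n_repeats = 3, seed = 2,
                n_restarts = 1, max_iter = 25, tol = 1e-3))
  series_ok <- lapply(co$parcel_series, function(r) lapply(r, standardize_ts))
  st_ok <- suppressWarnings(
    k_selection(series_ok, K_range = 3, n_repeats = 3, seed = 2,
                n_restarts = 1, max_iter = 25, tol = 1e-3))
  expect_lt(st_shuf$table$nmi_mean, st_ok$table$nmi_mean)
})
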