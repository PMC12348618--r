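#' Per-subject state expression
#'
#' The Pearson correlation between a subject's windowed fractional
#' occupancy of one state and the group appetite target, concatenated
#' across runs. Higher expression means the state's occupancy tracks
#' rising appetite more tightly. A constant FO series carries no
#' covariation and is returned as `NA` with a warning. Invariant to affine
#' rescaling of the target.
#'
#' @param fo subject's windowed FO values for the state (concatenated
#'   across runs), or a W x K matrix with `state` given.
#' @param target group appetite target per window (same concatenation).
#' @param state column to use when `fo` is a matrix.
#' @param min_windows minimum window count (default 10).
#' @return Correlation (scalar), possibly `NA`.
#' @export
state_expression <- function(fo, target, state = NULL, min_windows = 10) {
  if (is.matrix(fo)) {
    if (is.null(state)) stop("`state` is required for an FO matrix", call. = FALSE)
    fo <- fo[, state]
  }
  if (length(fo) != length(target)) stop("window counts differ", call. = FALSE)
  if (length(fo) < min_windows) {
    stop(sprintf("need at least %d windows", min_windows), call. = FALSE)
  }
  if (sd(fo) == 0) {
    warning("constant FO series: state expression undefined")
    return(NA_real_)
  }
  cor(fo, target)
}

#' State expression for every subject in a windowed dataset
#'
#' @param dataset a [windowed_dataset()].
#' @param state state column index.
#' @return Named vector of per-subject expressions.
#' @export
cohort_expression <- function(dataset, state) {
  vapply(dataset$FO_by_subject, function(FO) {
    suppressWarnings(state_expression(FO[, state], dataset$target))
  }, numeric(1))
}

#' Two-sample group comparison
#'
#' Student's two-sided two-sample t-test (pooled variance by default,
#' Welch optionally), as used for overweight/obese versus healthy-weight
#' contrasts.
#'
#' @param values numeric outcomes.
#' @param groups two-level grouping vector.
#' @param welch use the Welch correction.
#' @return List with `t`, `p`, `df`, `means`.
#' @export
group_compare <- function(values, groups, welch = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs at least 2 members", call. = FALSE)
  ht <- t.test(values ~ groups, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       means = ht$estimate)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the OLS residuals of `x` and `y` on the
#' covariates (with intercept); with no covariates this is the plain
#' Pearson correlation. p-value from the t distribution with
#' n - #covariates - 2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates optional matrix/data frame of controls.
#' @return List with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` lengths differ", call. = FALSE)
  k <- 0L
  if (!is.null(covariates)) {
    C <- as_confound_matrix(covariates)
    k <- ncol(C)
    if (n <= k + 2) stop("too few observations for the covariate count", call. = FALSE)
    design <- cbind(1, C)
    if (qr(design)$rank < ncol(design)) stop("rank-deficient covariates", call. = FALSE)
    sx0 <- sd(x); sy0 <- sd(y)
    x <- drop(qr.resid(qr(design), x))
    y <- drop(qr.resid(qr(design), y))
    # a variable that is itself a covariate leaves only rounding residue
    if (sd(x) < 1e-10 * max(sx0, 1)) x <- rep(0, n)
    if (sd(y) < 1e-10 * max(sy0, 1)) y <- rep(0, n)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance residual: partial correlation undefined")
    return(list(r = NA_real_, p = NA_real_, df = n - k - 2L))
  }
  r <- cor(x, y)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df), df = df)
}

#' One-way repeated-measures comparison of condition-wise FO
#'
#' One-way repeated-measures ANOVA (subject as blocking factor) on one
#' state's mean FO per condition, followed by pairwise paired t-tests with
#' BH-FDR correction. Used to check whether a state's occupancy
#' discriminates stimulus categories (e.g. mukbang / food presentation /
#' sport). Subjects with missing cells are dropped with a warning.
#'
#' @param fo_matrix subjects x conditions matrix of mean FO values.
#' @return List with `F`, `p`, `df`, and `pairwise` (data frame of paired
#'   contrasts with raw and FDR-adjusted p).
#' @export
condition_fo_compare <- function(fo_matrix) {
  fo_matrix <- as.matrix(fo_matrix)
  if (is.null(colnames(fo_matrix))) {
    colnames(fo_matrix) <- paste0("cond_", seq_len(ncol(fo_matrix)))
  }
  complete <- complete.cases(fo_matrix)
  if (any(!complete)) {
    warning(sprintf("dropping %d subject(s) with missing cells", sum(!complete)))
    fo_matrix <- fo_matrix[complete, , drop = FALSE]
  }
  n <- nrow(fo_matrix)
  C <- ncol(fo_matrix)
  if (n < 2 || C < 2) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  long <- data.frame(
    y = as.vector(fo_matrix),
    condition = factor(rep(colnames(fo_matrix), each = n)),
    subject = factor(rep(seq_len(n), times = C))
  )
  fit <- aov(y ~ condition + subject, data = long)
  tab <- summary(fit)[[1]]
  Fval <- tab["condition", "F value"]
  pval <- tab["condition", "Pr(>F)"]
  dfs <- c(tab["condition", "Df"], tab["Residuals", "Df"])
  # identical conditions: a 0/0 ratio of rounding residue is reported as F = 0
  total_ss <- sum((long$y - mean(long$y))^2)
  if (tab["condition", "Sum Sq"] <= 1e-12 * (total_ss + 1e-300)) {
    Fval <- 0
    pval <- 1
  }
  pairs <- combn(colnames(fo_matrix), 2)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], t = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    d <- fo_matrix[, pairs[1, i]] - fo_matrix[, pairs[2, i]]
    if (sd(d) == 0) {
      # constant difference: degenerate paired t
      pw$t[i] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pw$p[i] <- if (mean(d) == 0) 1 else 0
    } else {
      ht <- t.test(d)
      pw$t[i] <- unname(ht$statistic)
      pw$p[i] <- ht$p.value
    }
  }
  pw$p_fdr <- p.adjust(pw$p, method = "BH")
  list(F = unname(Fval), p = unname(pval), df = unname(dfs), pairwise = pw,
       n_subjects = n)
}

ols_paths <- function(X, M, Y, C) {
  # returns c(a, b, cprime, c) via least squares with intercept (+ covariates)
  d1 <- cbind(1, X, C)
  a <- qr.coef(qr(d1), M)[2]
  d2 <- cbind(1, X, M, C)
  bc <- qr.coef(qr(d2), Y)
  d3 <- cbind(1, X, C)
  cc <- qr.coef(qr(d3), Y)[2]
  c(a = unname(a), b = unname(bc[3]), cprime = unname(bc[2]), c = unname(cc))
}

#' Mediation analysis with a BCa bootstrap of the indirect effect
#'
#' Two-path mediation X -> M -> Y with optional covariates: `a` from
#' M ~ X (+cov), `b` and `c'` from Y ~ X + M (+cov), total `c` from
#' Y ~ X (+cov); the indirect effect is a*b. Subjects are resampled with
#' replacement and the indirect effect's 95% confidence interval is
#' bias-corrected and accelerated (bias from the bootstrap distribution's
#' median shift, acceleration from the jackknife skewness). The effect is
#' significant when the interval excludes zero; full mediation is reported
#' when additionally the direct path's percentile interval covers zero.
#'
#' @param X,M,Y predictor, mediator, outcome (one value per subject).
#' @param covariates optional controls entering every path regression.
#' @param B bootstrap iterations (study protocol: 10,000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return A `mediation_result` with `a`, `b`, `c`, `c_prime`, `indirect`,
#'   `ci_low`, `ci_high`, `significant`, `full_mediation`,
#'   `prop_mediated` = (c - c')/c, `B`, `boot` (indirect draws).
#' @export
mediation_bca <- function(X, M, Y, covariates = NULL, B = 10000, seed = 1,
                          conf = 0.95) {
  dat <- data.frame(X = X, M = M, Y = Y)
  C <- if (!is.null(covariates)) as_confound_matrix(covariates) else NULL
  ok <- complete.cases(if (is.null(C)) dat else cbind(dat, C))
  dat <- dat[ok, ]
  if (!is.null(C)) C <- C[ok, , drop = FALSE]
  n <- nrow(dat)
  if (n < 10) stop("need at least 10 complete cases", call. = FALSE)

  point <- ols_paths(dat$X, dat$M, dat$Y, C)
  if (anyNA(point)) {
    stop("collinear predictor/mediator/covariates: mediation paths unidentifiable",
         call. = FALSE)
  }
  indirect <- point["a"] * point["b"]

  boot_ab <- boot_cp <- numeric(B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      take <- sample.int(n, n, replace = TRUE)
      pb <- ols_paths(dat$X[take], dat$M[take], dat$Y[take],
                      if (is.null(C)) NULL else C[take, , drop = FALSE])
      boot_ab[b] <- pb["a"] * pb["b"]
      boot_cp[b] <- pb["cprime"]
    }
  })
  ok <- is.finite(boot_ab)
  if (!all(ok)) {
    warning(sprintf("dropping %d degenerate bootstrap draw(s)", sum(!ok)))
    boot_ab <- boot_ab[ok]
    boot_cp <- boot_cp[ok]
  }
  if (sd(boot_ab) == 0) {
    warning("degenerate bootstrap distribution of the indirect effect")
    ci <- c(indirect, indirect)
  } else {
    # BCa: bias correction from the fraction of draws below the estimate,
    # acceleration from the jackknife
    prop <- mean(boot_ab < indirect)
    z0 <- qnorm(min(max(prop, 1 / (B + 1)), B / (B + 1)))
    jack <- vapply(seq_len(n), function(i) {
      pj <- ols_paths(dat$X[-i], dat$M[-i], dat$Y[-i],
                      if (is.null(C)) NULL else C[-i, , drop = FALSE])
      pj["a"] * pj["b"]
    }, numeric(1))
    jm <- mean(jack)
    denom <- sum((jm - jack)^2)^1.5
    accel <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
    alpha <- (1 - conf) / 2
    zq <- qnorm(c(alpha, 1 - alpha))
    adj <- pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
    ci <- unname(quantile(boot_ab, adj))
  }
  cp_ci <- unname(quantile(boot_cp, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  significant <- ci[1] > 0 || ci[2] < 0
  structure(list(a = unname(point["a"]), b = unname(point["b"]),
                 c = unname(point["c"]), c_prime = unname(point["cprime"]),
                 indirect = unname(indirect), ci_low = ci[1], ci_high = ci[2],
                 significant = significant,
                 full_mediation = significant && cp_ci[1] <= 0 && cp_ci[2] >= 0,
                 prop_mediated = unname((point["c"] - point["cprime"]) / point["c"]),
                 c_prime_ci = cp_ci, B = B, n = n, conf = conf, boot = boot_ab),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation: a = %.3f, b = %.3f, c' = %.3f, c = %.3f\n  indirect a*b = %.3f, BCa %d%% CI [%.3f, %.3f]%s\n",
    x$a, x$b, x$c_prime, x$c, x$indirect, round(100 * x$conf), x$ci_low,
    x$ci_high,
    if (x$significant) if (x$full_mediation) " (full mediation)" else " (significant)" else ""))
  invisible(x)
}
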