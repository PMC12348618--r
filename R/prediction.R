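#' Logarithmically spaced ridge penalty grid
#'
#' Twenty candidate penalties between 0.001 and 1000 by default, matching
#' the study's hyperparameter search.
#'
#' @param n number of candidates.
#' @param min,max grid endpoints.
#' @return Increasing numeric vector.
#' @export
lambda_grid <- function(n = 20, min = 1e-3, max = 1e3) {
  exp(seq(log(min), log(max), length.out = n))
}

#' Regress confounds out of features, train-fitted
#'
#' Per-feature OLS on the confounds (with intercept) estimated on the
#' training rows only; training rows are replaced by their residuals and
#' test rows are adjusted with the training coefficients, so no information
#' flows from test to train. Constant or rank-deficient confound columns
#' are dropped with a warning.
#'
#' @param train_X training feature rows (matrix).
#' @param train_confounds matrix/data frame of confounds, rows aligned with
#'   `train_X`.
#' @param test_X,test_confounds optional test rows adjusted with the
#'   training fit.
#' @return List with `train`, `test` (or NULL), `coef` (including
#'   intercept), `kept` (confound columns used).
#' @export
residualize_confounds <- function(train_X, train_confounds,
                                  test_X = NULL, test_confounds = NULL) {
  train_X <- as.matrix(train_X)
  C <- as_confound_matrix(train_confounds)
  keep <- logical(ncol(C))
  for (j in seq_len(ncol(C))) keep[j] <- sd(C[, j]) > 0
  if (any(!keep)) {
    warning(sprintf("dropping constant confound(s): %s",
                    paste(colnames(C)[!keep], collapse = ", ")))
  }
  C <- C[, keep, drop = FALSE]
  design <- cbind(`(Intercept)` = 1, C)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[(qrd$rank + 1):ncol(design)]
    warning(sprintf("dropping rank-deficient confound(s): %s",
                    paste(colnames(design)[drop_idx], collapse = ", ")))
    design <- design[, -drop_idx, drop = FALSE]
    qrd <- qr(design)
  }
  coefs <- qr.coef(qrd, train_X)
  train_res <- train_X - design %*% coefs
  test_res <- NULL
  if (!is.null(test_X)) {
    test_X <- as.matrix(test_X)
    Ct <- as_confound_matrix(test_confounds)
    Ct <- Ct[, colnames(Ct) %in% colnames(C), drop = FALSE]
    dt <- cbind(`(Intercept)` = 1, Ct)[, colnames(design), drop = FALSE]
    test_res <- test_X - dt %*% coefs
  }
  list(train = train_res, test = test_res, coef = coefs,
       kept = colnames(design)[-1])
}

as_confound_matrix <- function(C) {
  if (is.null(C)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  if (is.data.frame(C)) {
    C <- vapply(C, function(col) {
      if (is.numeric(col)) col else as.numeric(factor(col))
    }, numeric(nrow(C)))
  }
  as.matrix(C)
}

#' Min-max scale features to [0, 1], train-fitted
#'
#' `(x - min_train) / (max_train - min_train)` per feature; the training
#' parameters are applied unchanged to the test rows, which may therefore
#' fall outside [0, 1] (no clipping). Zero-range features map to 0 with a
#' warning.
#'
#' @param train_X training rows.
#' @param test_X optional test rows.
#' @return List with `train`, `test` (or NULL), `min`, `max`.
#' @export
minmax_scale <- function(train_X, test_X = NULL) {
  train_X <- as.matrix(train_X)
  mins <- apply(train_X, 2, min)
  maxs <- apply(train_X, 2, max)
  rng <- maxs - mins
  zero <- rng == 0
  if (any(zero)) {
    warning(sprintf("%d zero-range feature(s) mapped to 0", sum(zero)))
    rng[zero] <- 1
  }
  scale_rows <- function(X) {
    out <- sweep(sweep(as.matrix(X), 2, mins), 2, rng, "/")
    out[, zero] <- 0
    out
  }
  list(train = scale_rows(train_X),
       test = if (!is.null(test_X)) scale_rows(test_X) else NULL,
       min = mins, max = maxs)
}

#' Ridge regression with an unpenalized intercept
#'
#' Closed-form solution `(X'X + lambda I)^-1 X'y` on centered data; the
#' intercept absorbs the means and is not shrunk.
#'
#' @param X feature rows (W x K).
#' @param y targets (length W).
#' @param lambda L2 penalty, >= 0.
#' @return A `ridge_model`: `weights`, `intercept`, `lambda`.
#' @export
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  G <- crossprod(Xc) + diag(lambda, ncol(X))
  w <- tryCatch(solve(G, crossprod(Xc, y - ybar)),
                error = function(e) {
                  stop("singular system; use lambda > 0 for collinear features",
                       call. = FALSE)
                })
  structure(list(weights = drop(w), intercept = ybar - sum(xbar * w),
                 lambda = lambda),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' Select the ridge penalty by joint accuracy and stability
#'
#' Subject-level inner cross-validation: for each candidate penalty, a
#' model is fitted on all but one subject fold and evaluated on the
#' held-out fold's rows. Accuracy is the mean Pearson correlation between
#' the true and predicted values over folds; stability is the mean pairwise
#' Pearson correlation among the fold models' weight vectors. Both are
#' min-max scaled across the grid and the chosen penalty minimizes the
#' Euclidean distance from the ideal point (1, 1) (ties: smaller penalty).
#' A fold with constant predictions scores accuracy 0.
#'
#' @param X,y preprocessed training rows and targets.
#' @param subjects subject id per row (folds never split a subject).
#' @param grid candidate penalties, increasing.
#' @param inner_folds number of subject folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @return List with `lambda`, `table` (per-penalty accuracy, stability,
#'   scaled values and distance), `n_degenerate` (folds with constant
#'   predictions).
#' @export
select_lambda <- function(X, y, subjects, grid = lambda_grid(),
                          inner_folds = 5, seed = 1) {
  X <- as.matrix(X)
  ids <- unique(subjects)
  if (length(ids) < inner_folds) {
    stop(sprintf("need at least %d training subjects for %d inner folds",
                 inner_folds, inner_folds), call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(ids))
  fold_of <- setNames(rep_len(seq_len(inner_folds), length(ids)), shuffled)
  row_fold <- fold_of[as.character(subjects)]

  acc <- stab <- numeric(length(grid))
  n_degenerate <- 0L
  for (li in seq_along(grid)) {
    rs <- numeric(inner_folds)
    Wmat <- matrix(0, ncol(X), inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- row_fold != f
      m <- ridge_fit(X[tr, , drop = FALSE], y[tr], grid[li])
      pred <- predict(m, X[!tr, , drop = FALSE])
      if (sd(pred) == 0 || sd(y[!tr]) == 0) {
        rs[f] <- 0
        n_degenerate <- n_degenerate + 1L
      } else {
        rs[f] <- cor(y[!tr], pred)
      }
      Wmat[, f] <- m$weights
    }
    acc[li] <- mean(rs)
    wc <- suppressWarnings(cor(Wmat))
    wc[!is.finite(wc)] <- 0
    stab[li] <- mean(wc[lower.tri(wc)])
  }
  scale01 <- function(x) if (diff(range(x)) == 0) rep(1, length(x)) else rescale_range(x)
  acc_s <- scale01(acc)
  stab_s <- scale01(stab)
  distance <- sqrt((1 - acc_s)^2 + (1 - stab_s)^2)
  best <- which(distance == min(distance))[1]  # grid ascending: ties -> smaller
  list(lambda = grid[best],
       table = data.frame(lambda = grid, accuracy = acc, stability = stab,
                          accuracy_scaled = acc_s, stability_scaled = stab_s,
                          distance = distance),
       n_degenerate = n_degenerate)
}

## row-expansion helpers -----------------------------------------------------

dataset_rows <- function(dataset, subjects, confounds) {
  idx <- match(subjects, dataset$covariates$subject_id)
  W <- vapply(dataset$FO_by_subject[idx], nrow, integer(1))
  X <- do.call(rbind, dataset$FO_by_subject[idx])
  y <- rep(list(dataset$target), length(idx))
  y <- unlist(y)
  subj <- rep(subjects, times = W)
  conf <- dataset$covariates[rep(idx, times = W), confounds, drop = FALSE]
  list(X = X, y = y, subjects = subj, confounds = conf, W = W)
}

#' Nested leave-one-subject-out cross-validated prediction
#'
#' Outer loop: each subject in turn is the full test set; confound
#' residualization and min-max scaling are fitted on the training rows and
#' applied to the held-out subject, the penalty is chosen by
#' [select_lambda()] on the training rows, the model is refitted on all
#' training rows, and the Pearson correlation between the held-out
#' subject's true and predicted windowed appetite is recorded. The
#' group-level penalty minimizes the mean inner-criterion distance across
#' outer folds; the group-level prediction is the dot product of the
#' group-mean (preprocessed) FO per window with the final model's weights.
#'
#' @param dataset a [windowed_dataset()].
#' @param grid penalty grid.
#' @param inner_folds inner subject folds.
#' @param seed RNG seed.
#' @param confounds covariate columns regressed out of each feature.
#' @return A `cv_result`: `per_subject_r`, `individual_mean_r`,
#'   `individual_se`, `group_r`, `lambda_per_fold`, `group_lambda`,
#'   `final_model`, `mean_distance_by_lambda`.
#' @export
loso_cv <- function(dataset, grid = lambda_grid(), inner_folds = 5, seed = 1,
                    confounds = c("age", "sex", "motion")) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  ids <- dataset$covariates$subject_id
  if (length(ids) < 3) stop("need at least 3 subjects", call. = FALSE)
  per_r <- setNames(numeric(length(ids)), ids)
  lam <- setNames(numeric(length(ids)), ids)
  dist_mat <- matrix(NA_real_, length(ids), length(grid))
  for (s in seq_along(ids)) {
    tr_ids <- ids[-s]
    tr <- dataset_rows(dataset, tr_ids, confounds)
    te <- dataset_rows(dataset, ids[s], confounds)
    rc <- suppressWarnings(
      residualize_confounds(tr$X, tr$confounds, te$X, te$confounds))
    sc <- suppressWarnings(minmax_scale(rc$train, rc$test))
    sel <- select_lambda(sc$train, tr$y, tr$subjects, grid, inner_folds,
                         seed = derive_seed(seed, s))
    dist_mat[s, ] <- sel$table$distance
    lam[s] <- sel$lambda
    model <- ridge_fit(sc$train, tr$y, sel$lambda)
    pred <- predict(model, sc$test)
    per_r[s] <- if (sd(pred) == 0) 0 else cor(te$y, pred)
  }
  mean_dist <- colMeans(dist_mat)
  group_lambda <- grid[which(mean_dist == min(mean_dist))[1]]

  all_rows <- dataset_rows(dataset, ids, confounds)
  rc <- suppressWarnings(residualize_confounds(all_rows$X, all_rows$confounds))
  sc <- suppressWarnings(minmax_scale(rc$train))
  final <- ridge_fit(sc$train, all_rows$y, group_lambda)
  Wn <- length(dataset$target)
  # subject-major rows: average the preprocessed features per window
  arr <- array(sc$train, dim = c(Wn, length(ids), ncol(sc$train)))
  group_FO <- apply(arr, c(1, 3), mean)
  group_pred <- predict(final, group_FO)
  group_r <- cor(dataset$target, group_pred)

  structure(list(per_subject_r = per_r,
                 individual_mean_r = mean(per_r),
                 individual_se = sd(per_r) / sqrt(length(per_r)),
                 group_r = group_r, lambda_per_fold = lam,
                 group_lambda = group_lambda, final_model = final,
                 mean_distance_by_lambda = setNames(mean_dist, signif(grid, 4)),
                 group_prediction = group_pred),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOSO prediction: individual r = %.3f +/- %.3f (mean +/- SE), group r = %.3f, lambda = %.4g\n",
              x$individual_mean_r, x$individual_se, x$group_r, x$group_lambda))
  invisible(x)
}

#' Cross-stimulus generalization of the appetite model
#'
#' Fits one model on all rows of the training dataset (confound
#' residualization and scaling fitted there, penalty given) and evaluates
#' per-subject and group-level prediction on an entirely independent
#' dataset. Run it in both directions to obtain the full generalization
#' picture.
#'
#' @param train_dataset,test_dataset [windowed_dataset()]s with the same
#'   number of state features.
#' @param lambda penalty (typically the group-level optimum from
#'   [loso_cv()]).
#' @param confounds covariate columns regressed out.
#' @return A `cv_result` (without inner-selection fields).
#' @export
cross_generalize <- function(train_dataset, test_dataset, lambda,
                             confounds = c("age", "sex", "motion")) {
  if (train_dataset$K != test_dataset$K) {
    stop("feature counts differ between datasets", call. = FALSE)
  }
  tr <- dataset_rows(train_dataset, train_dataset$covariates$subject_id, confounds)
  te_ids <- test_dataset$covariates$subject_id
  te <- dataset_rows(test_dataset, te_ids, confounds)
  rc <- suppressWarnings(residualize_confounds(tr$X, tr$confounds, te$X, te$confounds))
  sc <- suppressWarnings(minmax_scale(rc$train, rc$test))
  model <- ridge_fit(sc$train, tr$y, lambda)
  pred <- predict(model, sc$test)
  per_r <- vapply(seq_along(te_ids), function(i) {
    rows <- te$subjects == te_ids[i]
    if (sd(pred[rows]) == 0) 0 else cor(te$y[rows], pred[rows])
  }, numeric(1))
  names(per_r) <- te_ids
  Wn <- length(test_dataset$target)
  arr <- array(sc$test, dim = c(Wn, length(te_ids), ncol(sc$test)))
  group_pred <- predict(model, apply(arr, c(1, 3), mean))
  structure(list(per_subject_r = per_r,
                 individual_mean_r = mean(per_r),
                 individual_se = sd(per_r) / sqrt(length(per_r)),
                 group_r = cor(test_dataset$target, group_pred),
                 group_lambda = lambda, final_model = model),
            class = "cv_result")
}

#' Bootstrap stability of the state-feature weights
#'
#' Subjects are resampled with replacement (cluster bootstrap: windows
#' within a subject are dependent), the full preprocessing + ridge fit is
#' repeated inside each resample at the given penalty, and the coefficient
#' distribution per feature yields Z = mean/SD, two-tailed normal p-values
#' and BH-FDR flags. Degenerate resamples with a single distinct subject
#' are redrawn.
#'
#' @param dataset a [windowed_dataset()].
#' @param lambda penalty (group-level optimum).
#' @param B bootstrap samples (study protocol: 5000). Must be >= 2 for the
#'   SD to exist.
#' @param seed RNG seed.
#' @param q FDR level.
#' @param confounds covariate columns regressed out.
#' @return An `importance_result` data frame: `feature`, `mean`, `sd`, `z`,
#'   `p`, `sig`; attributes `B`, `n_redrawn`.
#' @export
bootstrap_importance <- function(dataset, lambda, B = 5000, seed = 1, q = 0.05,
                                 confounds = c("age", "sex", "motion")) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (B < 2) stop("`B` must be >= 2: the coefficient SD is undefined otherwise",
                  call. = FALSE)
  ids <- dataset$covariates$subject_id
  n <- length(ids)
  coefs <- matrix(NA_real_, B, dataset$K)
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        take <- sample.int(n, n, replace = TRUE)
        if (length(unique(take)) >= 2) break
        n_redrawn <- n_redrawn + 1L
      }
      rows <- dataset_rows(dataset, ids[take], confounds)
      rc <- suppressWarnings(residualize_confounds(rows$X, rows$confounds))
      sc <- suppressWarnings(minmax_scale(rc$train))
      coefs[b, ] <- ridge_fit(sc$train, rows$y, lambda)$weights
    }
  })
  m <- colMeans(coefs)
  s <- apply(coefs, 2, sd)
  z <- m / s
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(feature = colnames(dataset$FO_by_subject[[1]]) %||%
                      paste0("state_", seq_len(dataset$K)),
                    mean = m, sd = s, z = z, p = p, sig = bh_fdr(p, q))
  attr(out, "B") <- B
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR flags
#'
#' Standard step-up rule at level `q`; flags are monotone in p.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level.
#' @return Logical rejection flags.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH") <= q
}

dataset_rows_subjects <- function(dataset) dataset$covariates$subject_id
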