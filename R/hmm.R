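#' Standardize a parcel time series
#'
#' Per-column z-score within a subject/run, removing inter-individual
#' amplitude differences so fluctuation patterns are comparable across
#' subjects. The default uses the sample SD (denominator n - 1).
#'
#' @param X T x P numeric matrix.
#' @param sample_sd use the sample SD (default) or the population SD.
#' @return Standardized T x P matrix.
#' @export
standardize_ts <- function(X, sample_sd = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 time points", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- if (sample_sd) {
    sqrt(colSums(Xc^2) / (nrow(X) - 1))
  } else {
    sqrt(colMeans(Xc^2))
  }
  zero <- which(s == 0)
  if (length(zero)) {
    nm <- colnames(X)[zero] %||% as.character(zero)
    stop(sprintf("constant column(s): %s", paste(nm, collapse = ", ")), call. = FALSE)
  }
  sweep(Xc, 2, s, "/")
}

#' Fit a PCA projection retaining a target fraction of variance
#'
#' @param X (sum T) x P matrix, typically subject runs standardized and
#'   row-concatenated.
#' @param var_threshold fraction of variance to retain, in (0, 1]. D is the
#'   smallest component count whose cumulative explained variance reaches
#'   the threshold.
#' @return A `pca_projection`: `mean_vector`, `components` (P x D),
#'   `explained_ratio` (all P ratios), `D`, `var_threshold`.
#' @export
pca_fit <- function(X, var_threshold = 0.9) {
  if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold > 1) {
    stop("`var_threshold` must lie in (0, 1]", call. = FALSE)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  D <- which(cumsum(ratio) >= var_threshold - 1e-12)[1]
  structure(list(mean_vector = pc$center,
                 components = pc$rotation[, seq_len(D), drop = FALSE],
                 explained_ratio = ratio, D = D,
                 var_threshold = var_threshold),
            class = "pca_projection")
}

#' Project data through a fitted PCA
#' @param proj a [pca_fit()] result.
#' @param X T x P matrix.
#' @return T x D score matrix.
#' @export
pca_project <- function(proj, X) {
  sweep(as.matrix(X), 2, proj$mean_vector) %*% proj$components
}

#' Back-project PC scores to parcel space
#' @param proj a [pca_fit()] result.
#' @param Y T x D score matrix.
#' @return T x P matrix.
#' @export
pca_backproject <- function(proj, Y) {
  sweep(as.matrix(Y) %*% t(proj$components), 2, proj$mean_vector, "+")
}

## ---- Gaussian emission log densities -------------------------------------

#' Per-state Gaussian log densities for all frames.
#' Returns T x K matrix. Covariances are regularized upstream.
#' @noRd
gauss_logdens <- function(Y, means, covs) {
  T <- nrow(Y); D <- ncol(Y); K <- nrow(means)
  out <- matrix(0, T, K)
  for (k in seq_len(K)) {
    ch <- chol(covs[[k]])
    Yc <- sweep(Y, 2, means[k, ])
    Q <- Yc %*% backsolve(ch, diag(D))
    out[, k] <- -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(Q^2))
  }
  out
}

regularize_cov <- function(S, tries = 4) {
  eps <- 1e-6 * mean(diag(S))
  if (eps <= 0) eps <- 1e-8
  for (i in seq_len(tries)) {
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) return(S)
    S <- S + diag(eps, nrow(S))
    eps <- eps * 100
  }
  stop("covariance regularization failed", call. = FALSE)
}

## ---- EM fitting ----------------------------------------------------------

#' Fit a Gaussian-emission hidden Markov model by EM
#'
#' Baum-Welch with full state covariances, k-means initialization and
#' multiple restarts. `Y` may be a single T x D matrix or a list of
#' matrices; each list element is treated as an independent chain (the
#' forward-backward recursion restarts at every concatenation boundary with
#' the initial distribution), which is how subject runs are handled.
#'
#' @param Y matrix or list of matrices of PC scores.
#' @param K number of states (>= 1).
#' @param seed RNG seed controlling initialization.
#' @param n_restarts number of EM restarts; the best log-likelihood wins.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @return An `hmm_model`: `K`, `initial`, `transitions`, `means` (K x D),
#'   `covariances` (list of D x D), `loglik` (final), `loglik_trace`,
#'   `n_obs`, `converged`.
#' @export
hmm_fit <- function(Y, K, seed = 1, n_restarts = 5, max_iter = 100, tol = 1e-6) {
  seqs <- lapply(as_matrix_list(Y), as.matrix)
  stopifnot_scalar_count(K, "K")
  D <- ncol(seqs[[1]])
  Yall <- do.call(rbind, seqs)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- withr::with_seed(derive_seed(seed, rs), {
      try(em_run(seqs, Yall, K, D, max_iter, tol), silent = TRUE)
    })
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed", call. = FALSE)
  best$n_obs <- nrow(Yall)
  class(best) <- "hmm_model"
  best
}

em_run <- function(seqs, Yall, K, D, max_iter, tol) {
  T_all <- nrow(Yall)
  # k-means initialization; fall back to random assignment on failure
  assign0 <- tryCatch(
    kmeans(Yall, centers = K, nstart = 1, iter.max = 30)$cluster,
    error = function(e) sample.int(K, T_all, replace = TRUE)
  )
  means <- matrix(0, K, D)
  covs <- vector("list", K)
  pooled <- regularize_cov(stats::cov(Yall) + diag(1e-6, D))
  for (k in seq_len(K)) {
    idx <- which(assign0 == k)
    means[k, ] <- if (length(idx)) colMeans(Yall[idx, , drop = FALSE]) else
      Yall[sample.int(T_all, 1), ]
    covs[[k]] <- if (length(idx) > D + 1)
      regularize_cov(stats::cov(Yall[idx, , drop = FALSE]) + diag(1e-6, D))
    else pooled
  }
  A <- matrix(if (K > 1) 0.2 / (K - 1) else 0, K, K)
  diag(A) <- if (K > 1) 0.8 else 1
  init <- rep(1 / K, K)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logB_all <- gauss_logdens(Yall, means, covs)
    ll <- 0
    gamma_all <- matrix(0, T_all, K)
    xi_sum <- matrix(0, K, K)
    init_acc <- numeric(K)
    off <- 0L
    for (s in seq_along(seqs)) {
      Ts <- nrow(seqs[[s]])
      logB <- logB_all[(off + 1L):(off + Ts), , drop = FALSE]
      if (K == 1L) {
        fb <- list(gamma = matrix(1, Ts, 1), xi = matrix(Ts - 1, 1, 1),
                   loglik = sum(logB))
      } else {
        fb <- .fb_cpp(logB, init, A)
      }
      gamma_all[(off + 1L):(off + Ts), ] <- fb$gamma
      xi_sum <- xi_sum + fb$xi
      init_acc <- init_acc + fb$gamma[1, ]
      ll <- ll + fb$loglik
      off <- off + Ts
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    # M-step
    init <- init_acc / sum(init_acc)
    if (K > 1L) {
      rs <- rowSums(xi_sum)
      rs[rs == 0] <- 1
      A <- xi_sum / rs
    }
    Nk <- colSums(gamma_all)
    Nk[Nk < 1e-8] <- 1e-8
    means <- t(gamma_all) %*% Yall / Nk
    for (k in seq_len(K)) {
      Yc <- sweep(Yall, 2, means[k, ])
      W <- Yc * gamma_all[, k]
      covs[[k]] <- regularize_cov(crossprod(W, Yc) / Nk[k] + diag(1e-8, D))
    }
  }
  list(K = K, initial = init, transitions = A, means = means,
       covariances = covs, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("Gaussian HMM: K = %d, D = %d, loglik = %.2f (%sconverged, %d EM iterations)\n",
              x$K, ncol(x$means), x$loglik,
              if (x$converged) "" else "not ", length(x$loglik_trace)))
  invisible(x)
}

#' Decode state posteriors and the Viterbi path
#'
#' Forward-backward posteriors (`gamma`) and the max-product hard path for
#' one sequence or a list of sequences decoded independently.
#'
#' @param model an [hmm_fit()] result (or any list with `initial`,
#'   `transitions`, `means`, `covariances`).
#' @param Y matrix or list of matrices with `ncol` matching the model.
#' @return For a single matrix, a `state_path` with `gamma` (T x K) and
#'   `viterbi` (length T, values 1..K); for a list, a list of `state_path`s.
#' @export
hmm_decode <- function(model, Y) {
  single <- is.matrix(Y)
  seqs <- as_matrix_list(Y)
  K <- nrow(model$means)
  covs <- lapply(model$covariances, regularize_cov)
  out <- lapply(seqs, function(Ys) {
    Ys <- as.matrix(Ys)
    if (ncol(Ys) != ncol(model$means)) {
      stop("dimension mismatch between model and data", call. = FALSE)
    }
    logB <- gauss_logdens(Ys, model$means, covs)
    if (K == 1L) {
      return(structure(list(gamma = matrix(1, nrow(Ys), 1),
                            viterbi = rep(1L, nrow(Ys)), K = 1L),
                       class = "state_path"))
    }
    fb <- .fb_cpp(logB, model$initial, model$transitions)
    vit <- .viterbi_cpp(logB, log(pmax(model$initial, 1e-300)),
                        log(pmax(model$transitions, 1e-300)))
    structure(list(gamma = fb$gamma, viterbi = as.integer(vit),
                   loglik = fb$loglik, K = K), class = "state_path")
  })
  if (single) out[[1]] else out
}

#' Fractional occupancy of each state over an interval
#'
#' The proportion of time points within the interval assigned to each
#' state. The default counts hard (Viterbi) assignments; `mode = "soft"`
#' averages the posterior instead.
#'
#' @param path a `state_path` from [hmm_decode()], or an integer state
#'   vector (then `K` must be given).
#' @param interval integer TR indices (default: the whole path).
#' @param K number of states when `path` is a plain vector.
#' @param mode `"hard"` or `"soft"`.
#' @return Length-K simplex vector.
#' @export
fractional_occupancy <- function(path, interval = NULL, K = NULL, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (inherits(path, "state_path")) {
    K <- path$K
    hard <- path$viterbi
    gamma <- path$gamma
  } else {
    if (is.null(K)) stop("`K` is required for a plain state vector", call. = FALSE)
    hard <- as.integer(path)
    gamma <- NULL
  }
  n <- length(hard)
  interval <- interval %||% seq_len(n)
  if (length(interval) == 0) stop("empty interval", call. = FALSE)
  if (any(interval < 1 | interval > n)) stop("interval outside the path", call. = FALSE)
  if (mode == "soft") {
    if (is.null(gamma)) stop("soft mode needs posterior probabilities", call. = FALSE)
    return(colMeans(gamma[interval, , drop = FALSE]))
  }
  tabulate(hard[interval], nbins = K) / length(interval)
}
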