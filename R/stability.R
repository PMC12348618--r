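## Clustering-comparison metrics and split-half model stability.

pair_counts <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  list(n = n, tab = tab, ai = ai, bj = bj,
       M = choose(n, 2),
       M1 = sum(choose(ai, 2)), M2 = sum(choose(bj, 2)),
       w = sum(choose(tab, 2)))
}

#' Standardized Rand index (zRand) between two labelings
#'
#' The pair-counting agreement `w` (pairs co-clustered in both labelings),
#' standardized by its mean and variance under the permutation null that
#' fixes both labelings' cluster sizes (hypergeometric model). Invariant to
#' label renaming and symmetric in its arguments.
#'
#' @param a,b label vectors of equal length (>= 2).
#' @return The z-score; `NaN` with a warning when the null variance is zero
#'   (e.g. both sides a single cluster).
#' @export
zrand <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("labelings must have equal length >= 2", call. = FALSE)
  }
  pc <- pair_counts(a, b)
  n <- as.double(pc$n); M <- as.double(pc$M)
  M1 <- as.double(pc$M1); M2 <- as.double(pc$M2)
  mu <- M1 * M2 / M
  a3 <- sum(as.double(pc$ai)^3)
  b3 <- sum(as.double(pc$bj)^3)
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * a3
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * b3
  v <- M / 16 -
    (4 * M1 - 2 * M)^2 * (4 * M2 - 2 * M)^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    ((4 * M1 - 2 * M)^2 - 4 * C1 - 4 * M) *
      ((4 * M2 - 2 * M)^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (v <= 0) {
    warning("zRand undefined: zero permutation-null variance")
    return(NaN)
  }
  (pc$w - mu) / sqrt(v)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies (alternative normalizations: `"min"`, `"max"`, geometric
#' `"sqrt"`). A constant labeling on either side yields 0.
#'
#' @param a,b label vectors of equal length.
#' @param normalization entropy normalization rule.
#' @return Value in [0, 1].
#' @export
nmi <- function(a, b, normalization = c("mean", "min", "max", "sqrt")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("labelings must have equal length", call. = FALSE)
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (pa[row(tab)[nz]] * pb[col(tab)[nz]])))
  denom <- switch(normalization,
                  mean = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb),
                  sqrt = sqrt(ha * hb))
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement, 1 for identical partitions and
#' ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return The ARI.
#' @export
ari <- function(a, b) {
  pc <- pair_counts(a, b)
  expected <- as.double(pc$M1) * as.double(pc$M2) / as.double(pc$M)
  denom <- (as.double(pc$M1) + as.double(pc$M2)) / 2 - expected
  if (denom == 0) return(ifelse(pc$w == expected, 1, 0))
  (as.double(pc$w) - expected) / denom
}

#' Exact minimum-cost assignment by subset dynamic programming.
#' O(n * 2^n); exact and simple for the state counts used here (n <= 16).
#' @noRd
assignment_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n > 16) stop("assignment supported up to 16 states", call. = FALSE)
  full <- bitwShiftL(1L, n) - 1L
  dp <- rep(Inf, full + 1L)
  parent <- integer(full + 1L)
  dp[1L] <- 0
  popcount <- integer(full + 1L)
  for (m in 1:full) popcount[m + 1L] <- popcount[bitwAnd(m, m - 1L) + 1L] + 1L
  for (mask in 0:(full - 1L)) {
    d <- dp[mask + 1L]
    if (!is.finite(d)) next
    i <- popcount[mask + 1L] + 1L  # row to place next
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        nm <- bitwOr(mask, bit)
        val <- d + cost[i, j]
        if (val < dp[nm + 1L]) {
          dp[nm + 1L] <- val
          parent[nm + 1L] <- j
        }
      }
    }
  }
  perm <- integer(n)
  mask <- full
  for (i in n:1) {
    j <- parent[mask + 1L]
    perm[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  list(assignment = perm, cost = dp[full + 1L])
}

#' Match two sets of state activation maps
#'
#' Optimal one-to-one assignment maximizing the summed Pearson correlation
#' between matched maps (solved exactly), plus the activity concordance
#' index CI = mean matched correlation.
#'
#' @param mapsA,mapsB K x P activation-map matrices (rows are states).
#' @return List with `permutation` (row k of A matches row `permutation[k]`
#'   of B), `concordance` (CI), and the `similarity` matrix.
#' @export
match_states <- function(mapsA, mapsB) {
  mapsA <- as.matrix(mapsA)
  mapsB <- as.matrix(mapsB)
  if (!all(dim(mapsA) == dim(mapsB))) stop("maps must share dimensions", call. = FALSE)
  S <- suppressWarnings(cor(t(mapsA), t(mapsB)))
  S[!is.finite(S)] <- 0  # a flat map carries no pattern to match
  sol <- assignment_min(-S)
  matched <- S[cbind(seq_len(nrow(S)), sol$assignment)]
  list(permutation = sol$assignment, concordance = mean(matched), similarity = S)
}

#' Select the number of brain states by split-half stability
#'
#' For each K and repeat, subjects are split at random into two halves and
#' a model is fitted on each half (in a shared PCA space). Both models then
#' decode the same target set (the first half's data); agreement between
#' the two hard labelings (zRand, NMI) and between the matched activation
#' maps (concordance CI) quantifies stability. The composite score per K is
#' the mean of the three metrics after min-max scaling across the K range;
#' `chosen_K` maximizes it (ties: smaller K).
#'
#' @param series_by_subject list (one element per subject) of lists of
#'   standardized T x P run matrices.
#' @param K_range candidate state counts (study protocol: 5..12).
#' @param n_repeats random split-half repeats (study protocol: 10).
#' @param seed RNG seed.
#' @param var_threshold PCA variance threshold for the shared projection.
#' @param n_restarts,max_iter,tol EM settings passed to [hmm_fit()];
#'   defaults are lightened relative to a final fit since only stability is
#'   scored.
#' @return A `stability_report`: `table` (per-K mean/SD of each metric and
#'   the composite), `chosen_K`, `D` (shared PCA dimension), `n_repeats`.
#' @export
k_selection <- function(series_by_subject, K_range = 5:12, n_repeats = 10,
                        seed = 1, var_threshold = 0.9, n_restarts = 2,
                        max_iter = 40, tol = 1e-4) {
  n_sub <- length(series_by_subject)
  if (n_sub < 4) stop("need at least 4 subjects for split-half stability", call. = FALSE)
  flat <- lapply(series_by_subject, function(runs) do.call(rbind, as_matrix_list(runs)))
  proj <- pca_fit(do.call(rbind, flat), var_threshold)
  scores <- lapply(series_by_subject, function(runs) {
    lapply(as_matrix_list(runs), function(X) pca_project(proj, X))
  })
  parcel_runs <- lapply(series_by_subject, as_matrix_list)

  metrics <- array(NA_real_, dim = c(length(K_range), n_repeats, 3),
                   dimnames = list(K = K_range, NULL, c("zrand", "nmi", "concordance")))
  for (rep_i in seq_len(n_repeats)) {
    split <- withr::with_seed(derive_seed(seed, 7000L + rep_i), sample.int(n_sub))
    half1 <- sort(split[seq_len(ceiling(n_sub / 2))])
    half2 <- sort(split[(ceiling(n_sub / 2) + 1L):n_sub])
    Y1 <- unlist(scores[half1], recursive = FALSE)
    Y2 <- unlist(scores[half2], recursive = FALSE)
    target_Y <- Y1
    target_X <- do.call(rbind, unlist(parcel_runs[half1], recursive = FALSE))
    for (ki in seq_along(K_range)) {
      K <- K_range[ki]
      res <- try({
        m1 <- hmm_fit(Y1, K, seed = derive_seed(seed, 100L * rep_i + ki),
                      n_restarts = n_restarts, max_iter = max_iter, tol = tol)
        m2 <- hmm_fit(Y2, K, seed = derive_seed(seed, 100L * rep_i + ki + 50L),
                      n_restarts = n_restarts, max_iter = max_iter, tol = tol)
        p1 <- hmm_decode(m1, target_Y)
        p2 <- hmm_decode(m2, target_Y)
        v1 <- unlist(lapply(p1, `[[`, "viterbi"))
        v2 <- unlist(lapply(p2, `[[`, "viterbi"))
        maps1 <- state_maps_from_labels(target_X, v1, K)
        maps2 <- state_maps_from_labels(target_X, v2, K)
        c(suppressWarnings(zrand(v1, v2)), nmi(v1, v2),
          match_states(maps1, maps2)$concordance)
      }, silent = TRUE)
      if (!inherits(res, "try-error") && all(is.finite(res))) {
        metrics[ki, rep_i, ] <- res
      }
    }
  }

  surv <- apply(metrics[, , 1, drop = FALSE], 1, function(x) sum(is.finite(x)))
  if (any(surv < min(3, n_repeats))) {
    bad <- K_range[surv < min(3, n_repeats)]
    stop(sprintf("fewer than 3 surviving repeats for K = %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mean_m <- apply(metrics, c(1, 3), mean, na.rm = TRUE)
  sd_m <- apply(metrics, c(1, 3), sd, na.rm = TRUE)
  scaled <- vapply(colnames(mean_m), function(cn) {
    x <- mean_m[, cn]
    if (diff(range(x)) == 0) rep(0.5, length(x)) else rescale_range(x)
  }, numeric(length(K_range)))
  composite <- rowMeans(matrix(scaled, nrow = length(K_range)))
  chosen <- K_range[which.max(composite)]
  tab <- data.frame(K = K_range,
                    zrand_mean = mean_m[, "zrand"], zrand_sd = sd_m[, "zrand"],
                    nmi_mean = mean_m[, "nmi"], nmi_sd = sd_m[, "nmi"],
                    concordance_mean = mean_m[, "concordance"],
                    concordance_sd = sd_m[, "concordance"],
                    composite = composite)
  structure(list(table = tab, chosen_K = chosen, D = proj$D,
                 n_repeats = n_repeats, metrics = metrics),
            class = "stability_report")
}

#' Mean parcel pattern of each hard-assigned state.
#' @noRd
state_maps_from_labels <- function(X, labels, K) {
  maps <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (length(idx)) maps[k, ] <- colMeans(X[idx, , drop = FALSE])
  }
  maps
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Split-half stability over K = %s (%d repeats, D = %d): chosen K = %d\n",
              paste(range(x$table$K), collapse = ".."), x$n_repeats, x$D, x$chosen_K))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
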