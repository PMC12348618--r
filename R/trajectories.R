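#' Correlation similarity between BMI trajectories
#'
#' Pearson correlation between subjects' 6-point BMI series. Each series is
#' centred within subject first (correlation is location-invariant anyway;
#' the centred form is also the feature space for the validity indices), so
#' two subjects with the same change shape at different BMI levels are
#' maximally similar. `mode = "diff"` correlates month-to-month first
#' differences instead. Constant trajectories are excluded with a warning.
#'
#' @param M subjects x 6 matrix of monthly BMI values.
#' @param mode `"centered"` (default) or `"diff"`.
#' @return A `trajectory_similarity` object: `similarity` (correlations),
#'   `distance` (1 - r), `centered` (feature matrix), `kept` (row indices
#'   retained).
#' @export
trajectory_similarity <- function(M, mode = c("centered", "diff")) {
  mode <- match.arg(mode)
  M <- as.matrix(M)
  if (ncol(M) != 6) stop("expected 6 monthly BMI columns", call. = FALSE)
  feat <- if (mode == "diff") t(apply(M, 1, diff)) else M - rowMeans(M)
  keep <- which(apply(feat, 1, sd) > 0)
  if (length(keep) < nrow(M)) {
    warning(sprintf("excluding %d constant trajectory(ies)", nrow(M) - length(keep)))
  }
  feat <- feat[keep, , drop = FALSE]
  S <- cor(t(feat))
  structure(list(similarity = S, distance = 1 - S, centered = feat, kept = keep),
            class = "trajectory_similarity")
}

#' Average-linkage (UPGMA) hierarchical clustering of a distance matrix
#'
#' Thin wrapper over [stats::hclust()] with `method = "average"`, after
#' validating symmetry and a zero diagonal. Cutting the dendrogram at k
#' (via [stats::cutree()]) yields the cluster labels.
#'
#' @param D symmetric distance matrix with zero diagonal (or a
#'   [trajectory_similarity()] object).
#' @return An `hclust` tree.
#' @export
hclust_average <- function(D) {
  if (inherits(D, "trajectory_similarity")) D <- D$distance
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("distances must be finite", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-8)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  hclust(stats::as.dist(D), method = "average")
}

#' Davies-Bouldin and Calinski-Harabasz index curves
#'
#' For each k in `k_range`, labels come from cutting the tree; the indices
#' are computed on the feature vectors (the centred 6-point trajectories).
#' DB is the mean over clusters of the worst (s_i + s_j) / d_ij ratio of
#' centroid dispersions to centroid distance (lower is better; singleton
#' clusters have dispersion 0). CH is [between-SS / (k-1)] / [within-SS /
#' (n-k)] (higher is better).
#'
#' @param X feature matrix (e.g. `trajectory_similarity()$centered`).
#' @param tree an [hclust_average()] tree on the same rows.
#' @param k_range cluster counts to evaluate, within [2, n-1].
#' @return Data frame with columns `k`, `db`, `ch`.
#' @export
cluster_indices <- function(X, tree, k_range = 2:6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("`k_range` must lie within [2, n-1]", call. = FALSE)
  }
  out <- data.frame(k = k_range, db = NA_real_, ch = NA_real_)
  grand <- colMeans(X)
  total_ss <- sum(sweep(X, 2, grand)^2)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    labels <- cutree(tree, k = k)
    cent <- t(vapply(seq_len(k), function(c) colMeans(X[labels == c, , drop = FALSE]),
                     numeric(ncol(X))))
    s <- vapply(seq_len(k), function(c) {
      rows <- X[labels == c, , drop = FALSE]
      mean(sqrt(rowSums(sweep(rows, 2, cent[c, ])^2)))
    }, numeric(1))
    ratio <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b) {
        d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
        ratio[a, b] <- (s[a] + s[b]) / d
      }
    }
    out$db[i] <- mean(apply(ratio, 1, max))
    within <- sum(vapply(seq_len(k), function(c) {
      sum(sweep(X[labels == c, , drop = FALSE], 2, cent[c, ])^2)
    }, numeric(1)))
    between <- total_ss - within
    out$ch[i] <- (between / (k - 1)) / (within / (n - k))
  }
  out
}

#' Compare state expression between trajectory types
#'
#' Two-sample t-test of expression values between the BMI-increase type
#' and the BMI-stable type, as in [group_compare()].
#'
#' @param expression numeric expression values.
#' @param types trajectory type labels (two levels).
#' @param welch use the Welch correction.
#' @return List with `t`, `p`, `df`, `means`.
#' @export
compare_types <- function(expression, types, welch = FALSE) {
  group_compare(expression, types, welch = welch)
}
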