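#' Resample rating events onto the TR grid
#'
#' Bins continuous rating key presses into TR-length bins: each bin holds
#' the mean of the values whose onset falls in `[t*TR, (t+1)*TR)`; bins with
#' no press are coded 0 (absence of a press is treated as absence of
#' desire).
#'
#' @param events data frame with columns `onset` (seconds) and `value`.
#' @param TR repetition time in seconds.
#' @param T number of TRs in the run.
#' @param rater_id optional identifier carried along.
#' @return A `rater_trace`: list with `values` (length `T`) and `rater_id`.
#' @export
resample_events <- function(events, TR, T, rater_id = NULL) {
  stopifnot(is.data.frame(events) || is.null(events))
  if (is.null(events) || nrow(events) == 0) {
    return(structure(list(values = numeric(T), rater_id = rater_id),
                     class = "rater_trace"))
  }
  bad <- which(events$onset < 0 | events$onset >= T * TR)
  if (length(bad)) {
    stop(sprintf("event onset out of range [0, %g) at row(s) %s",
                 T * TR, paste(bad, collapse = ", ")), call. = FALSE)
  }
  bin <- floor(events$onset / TR) + 1L
  values <- numeric(T)
  agg <- tapply(events$value, bin, mean)
  values[as.integer(names(agg))] <- as.numeric(agg)
  structure(list(values = values, rater_id = rater_id), class = "rater_trace")
}

#' Z-score each rater's trace and average across raters
#'
#' Each trace is z-scored over time (no-press zeros included), then the
#' traces are averaged pointwise to give the group appetite course.
#' Constant traces carry no rank information and are excluded with a
#' warning.
#'
#' @param traces list of [resample_events()] traces (or plain numeric
#'   vectors) of equal length; at least 2 non-constant.
#' @param hrf optional kernel from [hrf_kernel()]; when supplied the
#'   convolved series is returned alongside.
#' @return A `group_appetite` object: `values` (z-scored group mean),
#'   `hrf_convolved` (or NULL), `n_raters_used`, `n_excluded`.
#' @export
group_average <- function(traces, hrf = NULL) {
  vals <- lapply(traces, function(tr) if (inherits(tr, "rater_trace")) tr$values else as.numeric(tr))
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) stop("traces must share the same length", call. = FALSE)
  keep <- vapply(vals, function(v) sd(v) > 0, logical(1))
  if (sum(keep) < 2L) stop("need at least 2 non-constant traces", call. = FALSE)
  if (any(!keep)) {
    warning(sprintf("excluded %d constant trace(s) from the group average", sum(!keep)))
  }
  z <- vapply(vals[keep], zscore, numeric(lens[1]))
  values <- rowMeans(z)
  conv <- if (!is.null(hrf)) hrf_convolve(values, hrf) else NULL
  structure(list(values = values, hrf_convolved = conv,
                 n_raters_used = sum(keep), n_excluded = sum(!keep)),
            class = "group_appetite")
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Difference of two gamma densities (peak minus undershoot, unit rate),
#' sampled on a `dt` grid over `length` seconds and normalised to unit sum
#' of absolute values. With the defaults the kernel peaks near 5 s, the
#' canonical BOLD latency.
#'
#' @param peak time-to-peak shape (s), default 6.
#' @param undershoot undershoot shape (s), default 16.
#' @param ratio peak-to-undershoot amplitude ratio, default 6.
#' @param length kernel support (s), default 32.
#' @param dt sampling step (s), must be > 0.
#' @return Numeric kernel vector of length `length/dt` (plus the t = 0
#'   sample).
#' @export
hrf_kernel <- function(peak = 6, undershoot = 16, ratio = 6, length = 32, dt = 1) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (length < peak) stop("`length` must cover the kernel peak", call. = FALSE)
  t <- seq(0, length, by = dt)
  h <- dgamma(t, shape = peak, rate = 1) - dgamma(t, shape = undershoot, rate = 1) / ratio
  h / sum(abs(h))
}

#' Causal convolution of a series with an HRF kernel
#'
#' Zero-padded causal convolution; output has the input's length. The first
#' few samples sit in the padding edge region, as is standard for filtered
#' event regressors.
#'
#' @param x numeric series.
#' @param kernel kernel from [hrf_kernel()].
#' @return Convolved series, same length as `x`.
#' @export
hrf_convolve <- function(x, kernel) {
  T <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(T)]
}

#' Spearman-Brown correction of a split-half correlation
#'
#' `2 * r / (1 + r)`: the projected reliability of the full set of raters
#' from the correlation between two half-sets. Monotone on (-1, 1], fixes
#' 0 and 1.
#'
#' @param r split-half correlation(s).
#' @return Corrected coefficient(s).
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of the group appetite course
#'
#' Per iteration the raters are split at random into two non-overlapping
#' halves (odd counts: the larger half takes the extra rater), each half is
#' averaged into a trace, the rank-order Spearman correlation across TRs is
#' computed and Spearman-Brown corrected. The observed statistic is the
#' mean corrected coefficient over iterations. The surrogate null adds, per
#' iteration, one further correlation after shuffling one half's rank
#' order; the right-tailed p compares the observed mean against the null
#' values with an add-one rule so p is never exactly 0.
#'
#' @param traces list of rater traces (vectors or `rater_trace`s), >= 4.
#' @param n_iter number of random splits (the study protocol uses 5000).
#' @param seed RNG seed.
#' @return A `reliability_result`: `mean_corrected_r`, `p_value`, `n_iter`,
#'   `null_distribution`, `observed_distribution`.
#' @export
split_half_reliability <- function(traces, n_iter = 5000, seed = 1) {
  vals <- lapply(traces, function(tr) if (inherits(tr, "rater_trace")) tr$values else as.numeric(tr))
  n <- length(vals)
  if (n < 4L) stop("need at least 4 raters for a split-half analysis", call. = FALSE)
  M <- do.call(cbind, vals)
  # Spearman = Pearson on ranks; pre-rank nothing (ranks depend on halves'
  # means), but ranking the half-mean traces per iteration is the cost.
  half <- n %/% 2L
  withr::with_seed(seed, {
    obs <- null <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n)
      h1 <- rowMeans(M[, idx[seq_len(half)], drop = FALSE])
      h2 <- rowMeans(M[, idx[(half + 1L):n], drop = FALSE])
      r1 <- rank(h1)
      r2 <- rank(h2)
      obs[it] <- spearman_brown(cor(r1, r2))
      null[it] <- spearman_brown(cor(r1, sample(r2)))
    }
  })
  observed <- mean(obs)
  p <- (1 + sum(null >= observed)) / (1 + n_iter)
  structure(list(mean_corrected_r = observed, p_value = p, n_iter = n_iter,
                 null_distribution = null, observed_distribution = obs),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Split-half reliability: corrected r = %.3f (p = %.4g, %d iterations)\n",
              x$mean_corrected_r, x$p_value, x$n_iter))
  invisible(x)
}
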