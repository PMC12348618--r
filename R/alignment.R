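#' Sliding-window scheme over a run
#'
#' Half-open, 0-based TR intervals `[i*step, i*step + length)`; trailing
#' TRs not covered by a full window are dropped so every window has the
#' same FO denominator. With length 5 and step 2 a 391-TR run yields 194
#' windows and a 287-TR run 142.
#'
#' @param T run length in TRs.
#' @param length window length in TRs (default 5).
#' @param step sliding step in TRs (default 2).
#' @return A `window_scheme`: `length_trs`, `step_trs`, `T`, `windows`
#'   (W x 2 matrix of 0-based `[start, end)` bounds), `n_windows`.
#' @export
make_windows <- function(T, length = 5, step = 2) {
  stopifnot_scalar_count(T, "T")
  stopifnot_scalar_count(length, "length")
  stopifnot_scalar_count(step, "step")
  if (T < length) stop("`T` must be at least the window length", call. = FALSE)
  n <- (T - length) %/% step + 1L
  starts <- (seq_len(n) - 1L) * step
  structure(list(length_trs = as.integer(length), step_trs = as.integer(step),
                 T = as.integer(T),
                 windows = cbind(start = starts, end = starts + length),
                 n_windows = as.integer(n)),
            class = "window_scheme")
}

#' Windowed fractional occupancies and appetite targets
#'
#' Per window: the FO row is the state fractional occupancy over the
#' window's TRs; the target is the mean of the group appetite series
#' (HRF-convolved when available) over the same TRs. Targets are
#' stimulus-locked and therefore identical across subjects.
#'
#' @param path a `state_path` or integer state vector for one run.
#' @param appetite a [group_average()] result or numeric series sharing the
#'   run's length.
#' @param scheme a [make_windows()] scheme for the run.
#' @param K state count when `path` is a plain vector.
#' @param mode FO mode, `"hard"` or `"soft"`.
#' @return A `windowed_features` object: `FO` (W x K), `target` (length W),
#'   `scheme`.
#' @export
windowed_features <- function(path, appetite, scheme, K = NULL,
                              mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "window_scheme"))
  series <- if (inherits(appetite, "group_appetite")) {
    appetite$hrf_convolved %||% appetite$values
  } else {
    as.numeric(appetite)
  }
  n <- if (inherits(path, "state_path")) length(path$viterbi) else length(path)
  if (n != length(series)) stop("path and appetite series lengths differ", call. = FALSE)
  if (n != scheme$T) stop("window scheme was built for a different run length", call. = FALSE)
  Kp <- if (inherits(path, "state_path")) path$K else K
  if (is.null(Kp)) stop("`K` is required for a plain state vector", call. = FALSE)
  W <- scheme$n_windows
  FO <- matrix(0, W, Kp)
  target <- numeric(W)
  for (w in seq_len(W)) {
    trs <- (scheme$windows[w, "start"] + 1L):scheme$windows[w, "end"]
    FO[w, ] <- fractional_occupancy(path, interval = trs, K = Kp, mode = mode)
    target[w] <- mean(series[trs])
  }
  colnames(FO) <- paste0("state_", seq_len(Kp))
  structure(list(FO = FO, target = target, scheme = scheme),
            class = "windowed_features")
}

#' Assemble a multi-subject windowed dataset for prediction
#'
#' Concatenates each subject's per-run windowed features (rows) and pairs
#' them with subject-level covariates. All subjects must share the same
#' window count and targets (stimulus-locked design).
#'
#' @param features_by_subject list (per subject) of one
#'   [windowed_features()] or a list of them (one per run, concatenated).
#' @param covariates data frame with one row per subject (must include
#'   `subject_id`; confound columns such as `age`, `sex`, `motion` are used
#'   by the prediction module).
#' @return A `windowed_dataset`: `FO_by_subject` (named list of W x K
#'   matrices), `target` (length W), `covariates`, `K`.
#' @export
windowed_dataset <- function(features_by_subject, covariates) {
  stopifnot(is.data.frame(covariates),
            length(features_by_subject) == nrow(covariates))
  fo <- vector("list", length(features_by_subject))
  target <- NULL
  for (i in seq_along(features_by_subject)) {
    wf <- features_by_subject[[i]]
    if (inherits(wf, "windowed_features")) wf <- list(wf)
    fo[[i]] <- do.call(rbind, lapply(wf, `[[`, "FO"))
    tgt <- unlist(lapply(wf, `[[`, "target"))
    if (is.null(target)) {
      target <- tgt
    } else if (!isTRUE(all.equal(target, tgt))) {
      stop("windowed targets differ across subjects; they must be stimulus-locked",
           call. = FALSE)
    }
  }
  names(fo) <- covariates$subject_id
  structure(list(FO_by_subject = fo, target = target, covariates = covariates,
                 K = ncol(fo[[1]])),
            class = "windowed_dataset")
}
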