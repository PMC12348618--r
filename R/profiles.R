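#' Characterize states by activation maps and functional connectivity
#'
#' For each state: the activation map is the mean standardized parcel
#' vector over the TRs hard-assigned to the state, pooled across all
#' entries; per subject, a Pearson FC matrix is computed over that
#' subject's assigned TRs when at least `min_trs` are available. The group
#' contrast per connection is a one-sample t-test across subjects of
#' (FC in the state minus the subject's mean FC over the other states),
#' BH-FDR corrected at `q` within each state.
#'
#' @param X_list list of standardized T x P matrices (one per subject/run).
#' @param path_list matching list of hard state vectors (or `state_path`s).
#' @param K number of states.
#' @param subject integer/character vector mapping entries of `X_list` to
#'   subjects (runs of one subject are pooled); defaults to one subject per
#'   entry.
#' @param networks optional parcel-network lookup (vector of network ids of
#'   length P) for a network-block reduction of the FC matrices.
#' @param min_trs minimum assigned TRs per subject for FC inclusion.
#' @param q FDR level for connection contrasts.
#' @return A `state_profiles` object: per state `activation_map`,
#'   `fc` (group-mean FC), `contrast` (list with `t`, `p`, `sig` matrices),
#'   `fc_network` (optional block means), `n_trs_used`, `empty` flag.
#' @export
state_profiles <- function(X_list, path_list, K, subject = NULL,
                           networks = NULL, min_trs = 10, q = 0.05) {
  stopifnot(length(X_list) == length(path_list))
  labels <- lapply(path_list, function(p) if (inherits(p, "state_path")) p$viterbi else as.integer(p))
  subject <- subject %||% seq_along(X_list)
  P <- ncol(X_list[[1]])
  subjects <- unique(subject)

  # pooled activation maps
  Xall <- do.call(rbind, X_list)
  lab_all <- unlist(labels)
  n_trs <- tabulate(lab_all, nbins = K)
  maps <- state_maps_from_labels(Xall, lab_all, K)

  # per-subject, per-state FC (lower-triangle vectors)
  lt <- lower.tri(matrix(0, P, P))
  fc_subj <- array(NA_real_, dim = c(length(subjects), K, sum(lt)))
  for (si in seq_along(subjects)) {
    idx <- which(subject == subjects[si])
    Xs <- do.call(rbind, X_list[idx])
    ls <- unlist(labels[idx])
    for (k in seq_len(K)) {
      rows <- which(ls == k)
      if (length(rows) >= min_trs) {
        fc_subj[si, k, ] <- suppressWarnings(cor(Xs[rows, , drop = FALSE]))[lt]
      }
    }
  }

  unpack <- function(v) {
    m <- diag(1, P)
    m[lt] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }

  profiles <- vector("list", K)
  for (k in seq_len(K)) {
    empty <- n_trs[k] == 0
    fc_mean <- if (!empty) {
      fc_mat <- matrix(fc_subj[, k, ], nrow = length(subjects))
      unpack(colMeans(fc_mat, na.rm = TRUE))
    } else NULL
    contrast <- NULL
    if (!empty) {
      # per-subject difference: state FC minus mean of the other states' FC
      diffs <- matrix(NA_real_, length(subjects), sum(lt))
      for (si in seq_along(subjects)) {
        own <- fc_subj[si, k, ]
        others <- matrix(fc_subj[si, setdiff(seq_len(K), k), ], nrow = K - 1)
        other_mean <- suppressWarnings(colMeans(others, na.rm = TRUE))
        if (all(is.finite(own)) && all(is.finite(other_mean))) {
          diffs[si, ] <- own - other_mean
        }
      }
      ok <- rowSums(is.finite(diffs)) > 0
      if (sum(ok) >= 3) {
        d <- diffs[ok, , drop = FALSE]
        m <- colMeans(d)
        se <- apply(d, 2, sd) / sqrt(nrow(d))
        tstat <- m / se
        pval <- 2 * pt(-abs(tstat), df = nrow(d) - 1)
        sig <- bh_fdr(pval, q)
        contrast <- list(t = unpack(tstat), p = unpack(pval),
                         sig = unpack(as.numeric(sig)) > 0.5, n_subjects = nrow(d))
        diag(contrast$sig) <- FALSE
      }
    }
    fc_net <- NULL
    if (!is.null(networks) && !empty && !is.null(fc_mean)) {
      ids <- sort(unique(networks))
      fc_net <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        blk <- fc_mean[networks == ids[a], networks == ids[b], drop = FALSE]
        if (a == b) {
          off <- blk[lower.tri(blk)]
          fc_net[a, b] <- if (length(off)) mean(off) else 1
        } else {
          fc_net[a, b] <- mean(blk)
        }
      }
    }
    profiles[[k]] <- list(state = k, activation_map = maps[k, ], fc = fc_mean,
                          fc_network = fc_net, contrast = contrast,
                          n_trs_used = n_trs[k], empty = empty)
  }
  structure(profiles, class = "state_profiles")
}

#' @export
print.state_profiles <- function(x, ...) {
  cat(sprintf("State profiles for %d states; TRs per state: %s\n", length(x),
              paste(vapply(x, `[[`, numeric(1), "n_trs_used"), collapse = ", ")))
  invisible(x)
}
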