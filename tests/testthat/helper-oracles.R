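# Independent oracles used to validate the package's core recursions.
# These deliberately use brute force / naive algorithms, never the package's
# own code paths.

# log-likelihood and posteriors of a Gaussian HMM by explicit enumeration of
# all K^T state paths
enum_hmm <- function(Y, initial, transitions, means, covariances) {
  T <- nrow(Y)
  K <- length(initial)
  dens <- sapply(seq_len(K), function(k) {
    S <- covariances[[k]]
    Si <- solve(S)
    dt <- determinant(S, logarithm = TRUE)$modulus
    vapply(seq_len(T), function(t) {
      d <- Y[t, ] - means[k, ]
      exp(-0.5 * (ncol(Y) * log(2 * pi) + dt + drop(t(d) %*% Si %*% d)))
    }, numeric(1))
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  total <- 0
  post <- matrix(0, T, K)
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    pr <- initial[p[1]] * prod(dens[cbind(seq_len(T), p)])
    if (T > 1) pr <- pr * prod(transitions[cbind(p[-T], p[-1])])
    total <- total + pr
    for (t in seq_len(T)) post[t, p[t]] <- post[t, p[t]] + pr
  }
  list(loglik = log(total), gamma = post / total)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  unname(out)
}

# brute-force best assignment maximizing the summed similarity
brute_match <- function(S) {
  perms <- all_perms(nrow(S))
  vals <- apply(perms, 1, function(p) sum(S[cbind(seq_len(nrow(S)), p)]))
  best <- which.max(vals)
  list(assignment = perms[best, ], value = vals[best])
}

# naive O(n^3) average-linkage agglomeration; returns merge heights and the
# flat labels at k clusters
naive_average_linkage <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1] - 1e-12) best <- c(d, i, j)
    }
    heights <- c(heights, best[1])
    if (length(clusters) == k) {
      labels <- integer(n)
      for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
      attr(heights, paste0("labels_k", k)) <- labels
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

naive_labels_at_k <- function(D, k) {
  h <- naive_average_linkage(D, k)
  attr(h, paste0("labels_k", k))
}

# pair-counting agreement statistic used by the permutation oracle
rand_w <- function(a, b) sum(choose(table(a, b), 2))

# a windowed prediction dataset with planted (independent-column) feature
# weights; the target is stimulus-locked and identical across subjects
make_planted_dataset <- function(n_subjects = 20, W = 180, K = 6,
                                 w_true = c(1, -0.8, 0.6, 0, 0, 0),
                                 target_noise = 0.2, subj_noise = 0.1,
                                 seed = 1) {
  withr::with_seed(seed, {
    group_X <- matrix(runif(W * K), W, K)
    target <- drop(group_X %*% w_true) + rnorm(W, 0, target_noise)
    feats <- lapply(seq_len(n_subjects), function(i) {
      FO <- group_X + matrix(rnorm(W * K, 0, subj_noise), W, K)
      colnames(FO) <- paste0("state_", seq_len(K))
      structure(list(FO = FO, target = target), class = "windowed_features")
    })
    cv <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
                     age = rnorm(n_subjects, 21, 1.5), sex = "F",
                     motion = abs(rnorm(n_subjects, 0.1, 0.03)))
    windowed_dataset(feats, cv)
  })
}

# small fast config for pipeline-level tests
tiny_synth_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_subjects = 6, n_raters = 6, T_per_run = c(60, 40), P = 30,
         K_true = 3, seed = seed),
    list(...))
  do.call(synth_config, args)
}
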