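#' Configuration for a synthetic food-cue viewing cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults define
#' the package's reference validation cohort: 6 well-separated brain states
#' with network-block activation patterns, 20 subjects watching two runs of
#' 500 TRs (TR = 1 s), 16 behavioural raters on a 3-point appetite scale,
#' and covariates carrying planted mediation paths and two BMI-trajectory
#' types. `synth_config_study()` returns the study-sized variant
#' (58 subjects, runs of 391 and 287 TRs, i.e. 194 and 142 sliding windows).
#'
#' @param n_subjects number of scanned subjects.
#' @param n_raters number of behavioural raters providing appetite events.
#' @param T_per_run integer vector of TR counts, one per run.
#' @param P number of cortical parcels.
#' @param K_true number of latent brain states (>= 2).
#' @param self_trans probability of remaining in the current state per TR.
#' @param jitter_eps baseline probability that a subject's state at a TR is
#'   replaced by a uniformly drawn state (idiosyncratic deviation from the
#'   stimulus-locked group path).
#' @param emission_sigma total observation noise SD per parcel. By default
#'   the noise is white (independent across parcels and TRs). Setting
#'   `noise_white_frac < 1` adds spatially correlated noise:
#'   `noise_factors` shared latent factors with a 1/j variance decay carry
#'   `1 - noise_white_frac` of the noise variance, mimicking the structured
#'   covariance of real BOLD noise (at the price of stability-based model
#'   selection latching onto the shared noise subspace).
#' @param appetite_weights length-`K_true` vector mapping states to appetite
#'   drive; default `seq(0, 1, length.out = K_true)`.
#' @param appetite_noise SD of per-rater noise added to the latent appetite
#'   course before thresholding into key presses.
#' @param coupling_bmi_r target correlation between the planted per-subject
#'   coupling gain and BMI (ignored when `gain_noise_sd` is given).
#' @param gain_noise_sd optional explicit SD of the noise on the coupling
#'   gain; overrides the value implied by `coupling_bmi_r`.
#' @param med_a,med_b,med_cprime planted mediation path coefficients:
#'   gain = `med_a`*BMI_std + noise; craving = `med_b`*gain +
#'   `med_cprime`*BMI_std + noise.
#' @param traj_types list of two 6-point BMI-offset templates (kg/m^2).
#' @param traj_noise SD of measurement noise on each monthly BMI point.
#' @param traj_gain_slope slope of the logistic link from standardised gain
#'   to P(trajectory type 1); the default 0.9 plants a between-type gain
#'   difference of Cohen's d ~ 0.8.
#' @param gain_jitter_mod in [0, 1): how strongly the coupling gain reduces a
#'   subject's deviation probability, `eps_i = jitter_eps * (1 -
#'   gain_jitter_mod * tanh(gain_std_i))`. Zero makes deviations
#'   gain-independent.
#' @param n_networks number of parcel networks in the lookup (Schaefer-style
#'   17 by default).
#' @param state_amplitude activation amplitude on a state's network blocks.
#' @param noise_factors,noise_white_frac noise covariance shape, see
#'   `emission_sigma`.
#' @param TR repetition time in seconds.
#' @param window_length smoothing width (TRs) for the latent appetite course.
#' @param seed RNG seed; a fixed seed reproduces the cohort bitwise.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 20, n_raters = 16, T_per_run = c(500, 500),
                         P = 100, K_true = 6, self_trans = 0.9, jitter_eps = 0.1,
                         emission_sigma = 0.5, appetite_weights = NULL,
                         appetite_noise = 0.3, coupling_bmi_r = 0.32,
                         gain_noise_sd = NULL, med_a = 0.5, med_b = 0.5,
                         med_cprime = 0,
                         traj_types = list(0.15 * (0:5), c(0, 0, 0, 0, -0.1, -0.2)),
                         traj_noise = 0.05, traj_gain_slope = 0.9,
                         gain_jitter_mod = 0.8, n_networks = 17,
                         state_amplitude = 1, noise_factors = 15,
                         noise_white_frac = 1, TR = 1, window_length = 5,
                         seed = 1) {
  stopifnot_scalar_count(n_subjects, "n_subjects")
  stopifnot_scalar_count(n_raters, "n_raters")
  stopifnot_scalar_count(P, "P")
  if (!is.numeric(K_true) || length(K_true) != 1L || K_true < 2) {
    stop("`K_true` must be a single integer >= 2", call. = FALSE)
  }
  if (P < K_true) stop("`P` must be >= `K_true`", call. = FALSE)
  for (p in c(self_trans, jitter_eps, noise_white_frac)) {
    if (!is.numeric(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(T_per_run < window_length)) {
    stop("every run must be at least `window_length` TRs long", call. = FALSE)
  }
  if (K_true > n_networks) {
    stop("`K_true` must not exceed `n_networks` (states use disjoint network blocks)",
         call. = FALSE)
  }
  if (is.null(appetite_weights)) appetite_weights <- seq(0, 1, length.out = K_true)
  if (length(appetite_weights) != K_true) {
    stop("`appetite_weights` must have length `K_true`", call. = FALSE)
  }
  if (!is.list(traj_types) || length(traj_types) != 2L ||
      any(lengths(traj_types) != 6L)) {
    stop("`traj_types` must be a list of two 6-point templates", call. = FALSE)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_raters = as.integer(n_raters),
    T_per_run = as.integer(T_per_run), P = as.integer(P),
    K_true = as.integer(K_true), self_trans = self_trans,
    jitter_eps = jitter_eps, emission_sigma = emission_sigma,
    appetite_weights = as.numeric(appetite_weights),
    appetite_noise = appetite_noise, coupling_bmi_r = coupling_bmi_r,
    gain_noise_sd = gain_noise_sd, med_a = med_a, med_b = med_b,
    med_cprime = med_cprime, traj_types = traj_types, traj_noise = traj_noise,
    traj_gain_slope = traj_gain_slope, gain_jitter_mod = gain_jitter_mod,
    n_networks = as.integer(n_networks), state_amplitude = state_amplitude,
    noise_factors = as.integer(noise_factors),
    noise_white_frac = noise_white_frac, TR = TR,
    window_length = as.integer(window_length), seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' @rdname synth_config
#' @param ... overrides passed on to [synth_config()].
#' @export
synth_config_study <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 58, n_raters = 38, T_per_run = c(391L, 287L))
  do.call(synth_config, utils::modifyList(defaults, args))
}

#' Parcel-to-network lookup used by the generator
#' @noRd
parcel_networks <- function(P, n_networks) {
  sizes <- rep(P %/% n_networks, n_networks)
  extra <- P %% n_networks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_networks), times = sizes)
}

#' Generate the ground-truth state model of a synthetic cohort
#'
#' Each state activates 1-3 disjoint network blocks of parcels (activation
#' `state_amplitude`, zero elsewhere), so pairwise state-mean cosine
#' similarity is exactly zero. Transitions are sticky with diagonal
#' `self_trans` and uniform off-diagonal mass; the initial distribution is
#' uniform.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `true_hmm` with elements `means` (K x P),
#'   `transitions`, `initial`, `networks` (parcel lookup data frame) and
#'   `state_networks`.
#' @export
gen_true_model <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  K <- cfg$K_true
  P <- cfg$P
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    lookup <- parcel_networks(P, cfg$n_networks)
    # deal disjoint network sets of size 1-3 to the states
    sizes <- sample(1:3, K, replace = TRUE)
    while (sum(sizes) > cfg$n_networks) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    pool <- sample(cfg$n_networks)
    state_nets <- vector("list", K)
    used <- 0L
    for (k in seq_len(K)) {
      state_nets[[k]] <- sort(pool[(used + 1L):(used + sizes[k])])
      used <- used + sizes[k]
    }
    means <- matrix(0, K, P)
    for (k in seq_len(K)) means[k, lookup %in% state_nets[[k]]] <- cfg$state_amplitude
  })
  A <- matrix((1 - cfg$self_trans) / (K - 1), K, K)
  diag(A) <- cfg$self_trans
  structure(list(
    means = means, transitions = A, initial = rep(1 / K, K),
    networks = data.frame(parcel_id = seq_len(P), network_17 = lookup),
    state_networks = state_nets, K = K, P = P
  ), class = "true_hmm")
}

#' @export
print.true_hmm <- function(x, ...) {
  cat(sprintf("Ground-truth HMM: %d states, %d parcels, self-transition %.3f\n",
              x$K, x$P, x$transitions[1, 1]))
  invisible(x)
}

sample_markov <- function(initial, transitions, T) {
  K <- length(initial)
  path <- integer(T)
  path[1] <- sample.int(K, 1, prob = initial)
  for (t in 2:T) path[t] <- sample.int(K, 1, prob = transitions[path[t - 1], ])
  path
}

#' Generate subject covariates with planted mediation and trajectory types
#'
#' BMI is drawn half from a healthy-weight and half from an overweight/obese
#' distribution (means 20.4 and 26.9 kg/m^2, mirroring the two-group design
#' of the study population the generator emulates). The coupling gain is
#' `med_a * BMI_std + noise` with the noise SD chosen so that
#' cor(gain, BMI) targets `coupling_bmi_r` (or set explicitly via
#' `gain_noise_sd`); post-viewing craving is `med_b * gain +
#' med_cprime * BMI_std + N(0, 1)`. Trajectory type 1 is assigned with
#' probability `plogis(traj_gain_slope * gain_std)` and the six monthly BMI
#' values are baseline BMI plus the type template plus measurement noise.
#'
#' @param cfg a [synth_config()].
#' @param n optional override of `cfg$n_subjects`.
#' @return A data frame with one row per subject.
#' @export
gen_covariates <- function(cfg, n = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- as.integer(n %||% cfg$n_subjects)
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    grp <- sample(rep(c("healthy", "overweight"), length.out = n))
    bmi <- ifelse(grp == "healthy", rnorm(n, 20.4, 1.2), rnorm(n, 26.9, 1.6))
    bmi_std <- if (n > 1) as.numeric(scale(bmi)) else 0
    sd_e <- cfg$gain_noise_sd %||%
      (if (cfg$med_a == 0 || cfg$coupling_bmi_r <= 0) 1 else
        abs(cfg$med_a) * sqrt(1 / cfg$coupling_bmi_r^2 - 1))
    gain <- cfg$med_a * bmi_std + rnorm(n, 0, sd_e)
    craving <- cfg$med_b * gain + cfg$med_cprime * bmi_std + rnorm(n)
    gain_std <- if (n > 1) as.numeric(scale(gain)) else 0
    type <- 1L + as.integer(runif(n) >= plogis(cfg$traj_gain_slope * gain_std))
    monthly <- t(vapply(seq_len(n), function(i) {
      bmi[i] + cfg$traj_types[[type[i]]] + rnorm(6, 0, cfg$traj_noise)
    }, numeric(6)))
    colnames(monthly) <- paste0("bmi_m", 1:6)
    eps_i <- pmin(pmax(cfg$jitter_eps * (1 - cfg$gain_jitter_mod * tanh(gain_std)), 0), 1)
    out <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      bmi = bmi, bmi_group = grp, age = rnorm(n, 20.8, 1.5), sex = "F",
      motion = abs(rnorm(n, 0.10, 0.03)), craving_post = craving,
      coupling_gain = gain, deviate_prob = eps_i, traj_type = type,
      stringsAsFactors = FALSE
    )
    cbind(out, as.data.frame(monthly))
  })
}

#' Generate a full synthetic cohort with recorded ground truth
#'
#' Samples a stimulus-locked group state path per run from the ground-truth
#' chain; each subject copies the group path, deviating independently per TR
#' with probability `eps_i` (gain-modulated, see [synth_config()]).
#' Observations are the state's parcel means plus spatially correlated
#' Gaussian noise. The latent appetite course is the state-to-appetite
#' weight of the group state, smoothed with a `window_length`-TR moving
#' average and rescaled to [0, 3]; each rater's key presses arise by adding
#' rater noise and thresholding at the 50th/70th/85th percentiles of the
#' noiseless course, so that all three ordinal levels occur.
#'
#' @param cfg a [synth_config()].
#' @param brain generate parcel time series (set `FALSE` for cheap
#'   behaviour-only cohorts).
#' @param ratings generate rater event streams.
#' @return An object of class `synth_cohort`; see Details for components.
#' @export
gen_cohort <- function(cfg, brain = TRUE, ratings = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  model <- gen_true_model(cfg)
  K <- cfg$K_true
  R <- length(cfg$T_per_run)

  group_path <- vector("list", R)
  for (r in seq_len(R)) {
    group_path[[r]] <- withr::with_seed(
      derive_seed(cfg$seed, 10L + r),
      sample_markov(model$initial, model$transitions, cfg$T_per_run[r])
    )
  }

  appetite_truth <- lapply(group_path, function(path) {
    raw <- cfg$appetite_weights[path]
    rescale_range(moving_average(raw, cfg$window_length), 0, 3)
  })

  covariates <- gen_covariates(cfg)
  eps_i <- covariates$deviate_prob

  # shared spatial noise loadings: factor j carries variance v_j per parcel
  q <- cfg$noise_factors
  v <- (1 / seq_len(q)) / sum(1 / seq_len(q)) *
    cfg$emission_sigma^2 * (1 - cfg$noise_white_frac)
  sigma0 <- cfg$emission_sigma * sqrt(cfg$noise_white_frac)
  loadings <- withr::with_seed(derive_seed(cfg$seed, 2L), {
    matrix(rnorm(cfg$P * q), cfg$P, q) %*% diag(sqrt(v), q)
  })

  subject_paths <- vector("list", cfg$n_subjects)
  parcel_series <- if (brain) vector("list", cfg$n_subjects) else NULL
  for (i in seq_len(cfg$n_subjects)) {
    withr::with_seed(derive_seed(cfg$seed, 1000L + i), {
      paths_i <- vector("list", R)
      series_i <- if (brain) vector("list", R) else NULL
      for (r in seq_len(R)) {
        T <- cfg$T_per_run[r]
        path <- group_path[[r]]
        dev <- runif(T) < eps_i[i]
        if (any(dev)) path[dev] <- sample.int(K, sum(dev), replace = TRUE)
        paths_i[[r]] <- path
        if (brain) {
          F <- matrix(rnorm(T * q), T, q)
          series_i[[r]] <- model$means[path, , drop = FALSE] +
            F %*% t(loadings) + matrix(rnorm(T * cfg$P, 0, sigma0), T, cfg$P)
          colnames(series_i[[r]]) <- sprintf("parcel_%03d", seq_len(cfg$P))
        }
      }
      subject_paths[[i]] <- paths_i
      if (brain) parcel_series[[i]] <- series_i
    })
  }
  names(subject_paths) <- covariates$subject_id
  if (brain) names(parcel_series) <- covariates$subject_id

  rater_events <- NULL
  if (ratings) {
    cuts <- quantile(unlist(appetite_truth), c(0.5, 0.7, 0.85), names = FALSE)
    rater_events <- vector("list", cfg$n_raters)
    for (j in seq_len(cfg$n_raters)) {
      withr::with_seed(derive_seed(cfg$seed, 5000L + j), {
        rater_events[[j]] <- lapply(seq_len(R), function(r) {
          truth <- appetite_truth[[r]]
          noisy <- truth + rnorm(length(truth), 0, cfg$appetite_noise)
          value <- findInterval(noisy, cuts)  # 0..3
          keep <- value > 0
          data.frame(
            onset = (which(keep) - 0.5) * cfg$TR,
            duration = cfg$TR,
            value = value[keep]
          )
        })
      })
    }
    names(rater_events) <- sprintf("rater-%03d", seq_len(cfg$n_raters))
  }

  structure(list(
    config = cfg, true_model = model, group_path = group_path,
    subject_paths = subject_paths, parcel_series = parcel_series,
    appetite_truth = appetite_truth, rater_events = rater_events,
    covariates = covariates, noise_loadings = loadings
  ), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d raters, runs of %s TRs, K_true = %d%s\n",
    x$config$n_subjects, x$config$n_raters,
    paste(x$config$T_per_run, collapse = "/"), x$config$K_true,
    if (is.null(x$parcel_series)) " (no brain data)" else ""
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Per-subject parcel series TSVs (`sub-XXX_run-X_parcels.tsv`), BIDS-style
#' rater event TSVs, a covariate TSV, the parcel-network lookup, and a
#' ground-truth JSON (group paths, state means, planted coefficients).
#'
#' @param cohort a [gen_cohort()] result with brain data.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  if (!is.null(cohort$parcel_series)) {
    for (i in seq_along(cohort$parcel_series)) {
      sid <- names(cohort$parcel_series)[i]
      for (r in seq_along(cohort$parcel_series[[i]])) {
        f <- file.path(dir, sprintf("%s_run-%d_parcels.tsv", sid, r))
        files <- c(files, tsv(as.data.frame(cohort$parcel_series[[i]][[r]]), f))
      }
    }
  }
  if (!is.null(cohort$rater_events)) {
    for (j in seq_along(cohort$rater_events)) {
      rid <- names(cohort$rater_events)[j]
      for (r in seq_along(cohort$rater_events[[j]])) {
        f <- file.path(dir, sprintf("%s_run-%d_events.tsv", rid, r))
        files <- c(files, tsv(cohort$rater_events[[j]][[r]], f))
      }
    }
  }
  files <- c(files, tsv(cohort$covariates, file.path(dir, "covariates.tsv")))
  files <- c(files, tsv(cohort$true_model$networks, file.path(dir, "parcel_networks.tsv")))
  truth <- list(
    seed = cohort$config$seed, K_true = cohort$config$K_true,
    group_path = cohort$group_path, state_means = cohort$true_model$means,
    transitions = cohort$true_model$transitions,
    appetite_weights = cohort$config$appetite_weights,
    med = list(a = cohort$config$med_a, b = cohort$config$med_b,
               cprime = cohort$config$med_cprime)
  )
  tf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, tf, digits = NA, auto_unbox = TRUE)
  files <- c(files, tf)
  invisible(files)
}
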