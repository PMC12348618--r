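#' Configuration of a full pipeline run
#'
#' Collects every fixed setting of the analysis; stages consume only
#' declared keys and the config is serialized into the run manifest. The
#' study-scale defaults (window 5 TRs / step 2, twenty penalties between
#' 0.001 and 1000, 5000 importance and reliability iterations, 10,000
#' mediation iterations, FDR q < 0.05, K evaluated over 5..12) can be
#' scaled down for quick runs.
#'
#' @param input_dir directory holding the input TSVs (as produced by
#'   [write_cohort()]).
#' @param out_dir output directory for stage artifacts.
#' @param TR repetition time (s).
#' @param window_length,window_step sliding-window geometry in TRs.
#' @param K fixed state count; if `NULL` the select-k stage chooses it.
#' @param K_range,k_repeats split-half stability settings.
#' @param var_threshold PCA variance threshold.
#' @param n_restarts,max_iter EM settings for the final fit.
#' @param grid ridge penalty grid.
#' @param inner_folds inner CV folds.
#' @param B_importance,B_mediation,n_iter_reliability bootstrap /
#'   permutation iteration counts.
#' @param fdr_q FDR level.
#' @param expression_state state used for state expression; `NULL` picks
#'   the significant importance feature with the largest positive Z.
#' @param confounds covariates regressed out of FO features.
#' @param seed master seed; stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir, TR = 1, window_length = 5,
                       window_step = 2, K = NULL, K_range = 5:12,
                       k_repeats = 10, var_threshold = 0.9, n_restarts = 5,
                       max_iter = 100, grid = lambda_grid(),
                       inner_folds = 5, B_importance = 5000,
                       B_mediation = 10000, n_iter_reliability = 5000,
                       fdr_q = 0.05, expression_state = NULL,
                       confounds = c("age", "sex", "motion"), seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

pipeline_paths <- function(cfg) {
  o <- cfg$out_dir
  list(
    group_appetite = file.path(o, "ratings", "group_appetite.tsv"),
    reliability = file.path(o, "ratings", "reliability.json"),
    stability = file.path(o, "brainstate", "stability.tsv"),
    model = file.path(o, "brainstate", "hmm_model.json"),
    paths = file.path(o, "brainstate", "state_paths.tsv"),
    features_dir = file.path(o, "align"),
    cv = file.path(o, "predict", "cv_results.json"),
    importance = file.path(o, "predict", "importance.tsv"),
    expression = file.path(o, "associate", "expression.tsv"),
    association = file.path(o, "associate", "association.json"),
    trajectories = file.path(o, "trajectories", "trajectory_types.tsv"),
    traj_indices = file.path(o, "trajectories", "cluster_indices.tsv"),
    manifest = file.path(o, "manifest.json")
  )
}

discover_inputs <- function(input_dir) {
  parcel <- sort(list.files(input_dir, pattern = "^sub-.*_parcels\\.tsv$",
                            full.names = TRUE))
  events <- sort(list.files(input_dir, pattern = "^rater-.*_events\\.tsv$",
                            full.names = TRUE))
  if (!length(parcel)) stop("no parcel series found in input_dir", call. = FALSE)
  meta <- function(fs, id_re) {
    data.frame(
      file = fs,
      id = sub(id_re, "\\1", basename(fs)),
      run = as.integer(sub(".*_run-(\\d+)_.*", "\\1", basename(fs))),
      stringsAsFactors = FALSE
    )
  }
  list(parcel = meta(parcel, "^(sub-[^_]+)_.*"),
       events = meta(events, "^(rater-[^_]+)_.*"),
       covariates = file.path(input_dir, "covariates.tsv"),
       networks = file.path(input_dir, "parcel_networks.tsv"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (ratings, brain-state fitting, window
#' alignment, prediction, association, trajectories), writing per-stage
#' TSV/JSON artifacts plus a manifest with the config, derived seeds and
#' content checksums. A stage whose artifacts already exist is skipped
#' unless `force`, so individual stages can be re-run by deleting their
#' outputs; upstream artifacts are left untouched.
#'
#' @param cfg a [run_config()].
#' @param force recompute even when artifacts exist.
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  p <- pipeline_paths(cfg)
  for (d in unique(c(dirname(unlist(p)), p$features_dir))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  inputs <- discover_inputs(cfg$input_dir)
  covariates <- read_covariates_tsv(inputs$covariates)
  runs <- sort(unique(inputs$parcel$run))
  timings <- list()
  done <- function(files) all(file.exists(unlist(files))) && !force

  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    r
  }

  # run lengths from the parcel series
  T_by_run <- vapply(runs, function(r) {
    nrow(read_parcel_tsv(inputs$parcel$file[inputs$parcel$run == r][1]))
  }, integer(1))

  ## ratings ------------------------------------------------------------
  if (!done(p[c("group_appetite", "reliability")])) {
    clock("ratings", {
      say("[ratings] resampling %d rater(s) over %d run(s)", nrow(inputs$events) /
            max(1, length(runs)), length(runs))
      kern <- hrf_kernel(dt = cfg$TR)
      app_rows <- list()
      rel <- list()
      for (r in runs) {
        ev_r <- inputs$events[inputs$events$run == r, ]
        traces <- lapply(ev_r$file, function(f) {
          resample_events(read_events_tsv(f), cfg$TR, T_by_run[r])
        })
        ga <- group_average(traces, hrf = kern)
        app_rows[[r]] <- data.frame(run = r, tr = seq_len(T_by_run[r]),
                                    appetite = ga$values,
                                    appetite_hrf = ga$hrf_convolved)
        rel[[paste0("run", r)]] <- unclass(
          split_half_reliability(traces, n_iter = cfg$n_iter_reliability,
                                 seed = derive_seed(cfg$seed, 20L + r))
        )[c("mean_corrected_r", "p_value", "n_iter")]
      }
      write_tsv(do.call(rbind, app_rows), p$group_appetite)
      write_json_out(rel, p$reliability)
    })
  } else say("[ratings] artifacts exist, skipping")

  ## brainstate ----------------------------------------------------------
  if (!done(p[c("model", "paths")])) {
    clock("brainstate", {
      subj_ids <- unique(inputs$parcel$id)
      say("[brainstate] standardizing %d subject(s)", length(subj_ids))
      series <- lapply(subj_ids, function(sid) {
        lapply(runs, function(r) {
          f <- inputs$parcel$file[inputs$parcel$id == sid & inputs$parcel$run == r]
          standardize_ts(read_parcel_tsv(f))
        })
      })
      names(series) <- subj_ids
      K <- cfg$K
      if (is.null(K)) {
        say("[brainstate] selecting K over %s", paste(range(cfg$K_range), collapse = ".."))
        stab <- k_selection(series, K_range = cfg$K_range,
                            n_repeats = cfg$k_repeats,
                            seed = derive_seed(cfg$seed, 30L),
                            var_threshold = cfg$var_threshold)
        write_tsv(stab$table, p$stability)
        K <- stab$chosen_K
      }
      proj <- pca_fit(do.call(rbind, unlist(series, recursive = FALSE)),
                      cfg$var_threshold)
      scores <- lapply(series, function(s) lapply(s, function(X) pca_project(proj, X)))
      flat <- unlist(scores, recursive = FALSE)
      say("[brainstate] fitting K = %d on D = %d components", K, proj$D)
      model <- hmm_fit(flat, K, seed = derive_seed(cfg$seed, 31L),
                       n_restarts = cfg$n_restarts, max_iter = cfg$max_iter)
      paths <- lapply(scores, function(s) hmm_decode(model, s))
      path_rows <- do.call(rbind, lapply(subj_ids, function(sid) {
        do.call(rbind, lapply(seq_along(runs), function(ri) {
          data.frame(subject_id = sid, run = runs[ri],
                     tr = seq_len(T_by_run[runs[ri]]),
                     state = paths[[sid]][[ri]]$viterbi)
        }))
      }))
      write_tsv(path_rows, p$paths)
      write_json_out(list(K = K, D = proj$D,
                          explained = sum(proj$explained_ratio[seq_len(proj$D)]),
                          initial = model$initial,
                          transitions = model$transitions,
                          loglik = model$loglik), p$model)
    })
  } else say("[brainstate] artifacts exist, skipping")

  ## align ---------------------------------------------------------------
  feature_files <- file.path(p$features_dir,
                             paste0(unique(inputs$parcel$id), "_features.tsv"))
  if (!done(feature_files)) {
    clock("align", {
      say("[align] windowing (length %d, step %d)", cfg$window_length, cfg$window_step)
      app <- read.delim(p$group_appetite)
      path_rows <- read.delim(p$paths)
      K <- jsonlite::read_json(p$model)$K
      for (sid in unique(inputs$parcel$id)) {
        rows <- lapply(runs, function(r) {
          scheme <- make_windows(T_by_run[r], cfg$window_length, cfg$window_step)
          st <- path_rows$state[path_rows$subject_id == sid & path_rows$run == r]
          tgt <- app$appetite_hrf[app$run == r]
          wf <- windowed_features(st, tgt, scheme, K = K)
          data.frame(run = r, window = seq_len(nrow(wf$FO)), wf$FO,
                     target = wf$target)
        })
        write_tsv(do.call(rbind, rows),
                  file.path(p$features_dir, paste0(sid, "_features.tsv")))
      }
    })
  } else say("[align] artifacts exist, skipping")

  read_dataset <- function() {
    subj_ids <- unique(inputs$parcel$id)
    feats <- lapply(subj_ids, function(sid) {
      df <- read.delim(file.path(p$features_dir, paste0(sid, "_features.tsv")))
      fo_cols <- grep("^state_", names(df), value = TRUE)
      list(FO = as.matrix(df[fo_cols]), target = df$target)
    })
    cv <- covariates[match(subj_ids, covariates$subject_id), ]
    windowed_dataset(lapply(feats, function(f) {
      structure(list(FO = f$FO, target = f$target), class = "windowed_features")
    }), cv)
  }

  ## predict -------------------------------------------------------------
  if (!done(p[c("cv", "importance")])) {
    clock("predict", {
      say("[predict] nested LOSO ridge regression")
      ds <- read_dataset()
      cvres <- loso_cv(ds, grid = cfg$grid, inner_folds = cfg$inner_folds,
                       seed = derive_seed(cfg$seed, 40L), confounds = cfg$confounds)
      imp <- bootstrap_importance(ds, cvres$group_lambda, B = cfg$B_importance,
                                  seed = derive_seed(cfg$seed, 41L),
                                  q = cfg$fdr_q, confounds = cfg$confounds)
      write_json_out(list(per_subject_r = as.list(cvres$per_subject_r),
                          individual_mean_r = cvres$individual_mean_r,
                          individual_se = cvres$individual_se,
                          group_r = cvres$group_r,
                          group_lambda = cvres$group_lambda,
                          weights = as.list(setNames(cvres$final_model$weights,
                                                     imp$feature))), p$cv)
      write_tsv(imp, p$importance)
    })
  } else say("[predict] artifacts exist, skipping")

  ## associate -----------------------------------------------------------
  if (!done(p[c("expression", "association")])) {
    clock("associate", {
      ds <- read_dataset()
      imp <- read.delim(p$importance)
      state <- cfg$expression_state
      if (is.null(state)) {
        cand <- which(imp$sig & imp$z > 0)
        state <- if (length(cand)) cand[which.max(imp$z[cand])] else which.max(abs(imp$z))
      }
      say("[associate] state expression for state %d", state)
      expr <- cohort_expression(ds, state)
      cv <- ds$covariates
      write_tsv(data.frame(subject_id = names(expr), state = state,
                           expression = unname(expr)), p$expression)
      grp <- if ("bmi_group" %in% names(cv)) {
        group_compare(expr, cv$bmi_group)
      } else NULL
      pc_raw <- partial_correlation(expr, cv$bmi)
      pc_age <- partial_correlation(expr, cv$bmi, cv["age"])
      med <- if ("craving_post" %in% names(cv) && nrow(cv) >= 10) {
        unclass(mediation_bca(cv$bmi, expr, cv$craving_post,
                              covariates = cv["age"], B = cfg$B_mediation,
                              seed = derive_seed(cfg$seed, 42L)))[
          c("a", "b", "c", "c_prime", "indirect", "ci_low", "ci_high",
            "significant", "full_mediation", "prop_mediated", "B")]
      } else NULL
      write_json_out(list(expression_state = state,
                          group_t = grp,
                          bmi_r = pc_raw, bmi_r_age_adjusted = pc_age,
                          mediation = med), p$association)
    })
  } else say("[associate] artifacts exist, skipping")

  ## trajectories ---------------------------------------------------------
  if (!done(p[c("trajectories", "traj_indices")])) {
    clock("trajectories", {
      say("[trajectories] clustering 6-point BMI series")
      mcols <- paste0("bmi_m", 1:6)
      if (all(mcols %in% names(covariates))) {
        M <- as.matrix(covariates[mcols])
        ts <- trajectory_similarity(M)
        tree <- hclust_average(ts)
        labels <- cutree(tree, k = 2)
        # convention: type 1 is the cluster with the larger mean BMI slope
        slopes <- tapply(apply(ts$centered, 1, function(z) coef(lm(z ~ seq_len(6)))[2]),
                         labels, mean)
        if (which.max(slopes) != 1) labels <- 3L - labels
        idx <- cluster_indices(ts$centered, tree,
                               k_range = 2:min(6, nrow(M) - 1))
        expr_df <- read.delim(p$expression)
        types_t <- compare_types(expr_df$expression[ts$kept], labels)
        write_tsv(data.frame(subject_id = covariates$subject_id[ts$kept],
                             traj_type = labels), p$trajectories)
        idx$type_diff_t <- types_t$t
        idx$type_diff_p <- types_t$p
        write_tsv(idx, p$traj_indices)
      } else {
        say("[trajectories] no monthly BMI columns; stage skipped")
        write_tsv(data.frame(), p$trajectories)
        write_tsv(data.frame(), p$traj_indices)
      }
    })
  } else say("[trajectories] artifacts exist, skipping")

  ## manifest ------------------------------------------------------------
  artifacts <- c(setdiff(unlist(p), c(p$manifest, p$features_dir)),
                 list.files(p$features_dir, full.names = TRUE))
  artifacts <- artifacts[file.exists(artifacts)]
  checksums <- vapply(artifacts, function(f) fnv1a(readLines(f, warn = FALSE)),
                      character(1))
  cfg_ser <- cfg
  cfg_ser$grid <- as.numeric(cfg_ser$grid)
  class(cfg_ser) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("statecue")),
    config = cfg_ser,
    config_hash = fnv1a(jsonlite::toJSON(cfg_ser, digits = NA, auto_unbox = TRUE)),
    seed = cfg$seed,
    inputs = basename(c(inputs$parcel$file, inputs$events$file)),
    artifacts = as.list(setNames(unname(checksums), basename(names(checksums)))),
    timings_s = timings
  )
  write_json_out(manifest, p$manifest)
  invisible(manifest)
}
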