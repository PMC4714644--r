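#' End-to-end experiment configuration
#'
#' Bundles everything one experiment needs: the synthetic-cohort settings
#' (or paths to existing data), the feature representation, the model type,
#' how the positive-fraction parameter `r` is chosen, optional recursive
#' feature elimination, and a global seed from which every stage derives
#' its own.
#'
#' @param map_config A [map_sim_config()] describing the synthetic cohort,
#'   or `NULL` when `map_paths` is given.
#' @param map_paths Optional named list `list(manifest = , dir = )` pointing
#'   at NIfTI maps on disk (one file per subject per contrast).
#' @param scores_path Optional CSV of outcome scores; with `NULL` a
#'   synthetic table is generated to match the cohort.
#' @param feature_type `"BoW_controls_only"` (dictionary built from the
#'   control cohort only), `"BoW_all_subjects"`, or `"VOX"`.
#' @param contrasts Contrast name(s); several are concatenated in the given
#'   order into one combined feature vector.
#' @param model `"semisupervised"` or `"supervised"`.
#' @param r Fixed positive fraction for the semi-supervised model.
#' @param r_grid Optional grid; when supplied, `r` is selected per outer
#'   fold by nested LOOCV instead of being fixed.
#' @param rfe Optional [rfe_config()]; when supplied, feature selection
#'   runs independently inside every cross-validation fold.
#' @param out_dir Output directory for artifacts.
#' @param seed Global integer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(map_config = map_sim_config(),
                              map_paths = NULL, scores_path = NULL,
                              feature_type = c("BoW_controls_only",
                                               "BoW_all_subjects", "VOX"),
                              contrasts = "speech_vs_silence",
                              model = c("semisupervised", "supervised"),
                              r = 0.6, r_grid = NULL, rfe = NULL,
                              out_dir = NULL, seed = 1L) {
  feature_type <- match.arg(feature_type)
  model <- match.arg(model)
  if (feature_type == "BoW_controls_only" && !is.null(map_config) &&
      map_config$n_controls < 1) {
    stop_bowsvm("BoW_controls_only requires a control cohort",
                "bowsvm_config_error")
  }
  if (!is.null(rfe)) stopifnot(inherits(rfe, "rfe_config"))
  structure(list(map_config = map_config, map_paths = map_paths,
                 scores_path = scores_path, feature_type = feature_type,
                 contrasts = contrasts, model = model, r = r,
                 r_grid = r_grid, rfe = rfe, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# deterministic per-stage seeds derived from the global seed
stage_seed <- function(seed, stage) {
  (seed * 7919L + stage * 104729L) %% 2000000000L
}

#' Prepare all inputs for an experiment
#'
#' Runs the data and feature stages of [run_experiment()] and returns the
#' in-memory objects: feature matrices split by cohort role, the outcome
#' table, the k-means label assignment, and the dictionaries.
#'
#' @param cfg An [experiment_config()].
#' @return A list with `X_lab`, `y_lab`, `X_unlab`, `X_controls`,
#'   `score_table`, `labels`, `dictionaries`, `cohorts`, `outcome_sums`.
#' @export
prepare_experiment_data <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  mc <- cfg$map_config
  cohorts <- lapply(seq_along(cfg$contrasts), function(i) {
    mc_i <- mc
    mc_i$seed <- stage_seed(cfg$seed, i)
    generate_cohort_maps(validate_map_sim_config(mc_i),
                         contrast_name = cfg$contrasts[i])
  })
  names(cohorts) <- cfg$contrasts
  manifest <- cohorts[[1]]$manifest

  score_table <- if (is.null(cfg$scores_path)) {
    generate_outcome_table(n_effective = mc$n_effective,
                           n_ineffective = mc$n_ineffective,
                           seed = stage_seed(cfg$seed, 100L))
  } else {
    load_scores(cfg$scores_path)
  }
  # participants map to labeled patient subjects: planted-ineffective rows
  # to the ineffective subjects, planted-effective rows to the effective
  ord <- order(match(score_table$planted %||%
                       rep("effective", nrow(score_table)),
                     c("ineffective", "effective")))
  subj_ineff <- manifest$subject_id[manifest$group == "ineffective"]
  subj_eff <- manifest$subject_id[manifest$group == "effective"]
  score_table$subject_id <- NA_character_
  score_table$subject_id[ord] <- c(subj_ineff, subj_eff)

  labels <- kmeans_labels(score_table, seed = stage_seed(cfg$seed, 200L))

  feats <- lapply(cohorts, function(co) {
    if (cfg$feature_type == "VOX") {
      list(features = vox_features(co), dictionary = NULL)
    } else {
      builders <- if (cfg$feature_type == "BoW_controls_only") {
        co$maps[co$manifest$group == "control"]
      } else {
        co$maps
      }
      d <- build_dictionary(builders)
      list(features = featurize(d, co), dictionary = d)
    }
  })
  X <- do.call(cbind, lapply(feats, `[[`, "features"))
  rownames(X) <- manifest$subject_id
  colnames(X) <- paste0("f", seq_len(ncol(X)))

  lab_rows <- match(score_table$subject_id, manifest$subject_id)
  list(
    X_lab = X[lab_rows, , drop = FALSE],
    y_lab = labels$label,
    X_unlab = X[manifest$group == "unlabeled", , drop = FALSE],
    X_controls = X[manifest$group == "control", , drop = FALSE],
    score_table = score_table, labels = labels,
    dictionaries = lapply(feats, `[[`, "dictionary"),
    cohorts = cohorts, outcome_sums = score_table$sum,
    n_features = ncol(X))
}

# LOOCV with feature selection repeated independently inside every fold;
# fold weight vectors are re-embedded into the full feature space so that
# stability measures stay comparable across folds
loocv_with_rfe <- function(X_lab, y_lab, X_unlab, train_cfg, rfe_cfg,
                           trainer, outcome_sums = NULL) {
  M <- nrow(X_lab)
  p <- ncol(X_lab)
  models <- vector("list", M)
  selections <- vector("list", M)
  rows <- vector("list", M)
  for (k in seq_len(M)) {
    res <- tryCatch(
      rfe(X_lab[-k, , drop = FALSE], y_lab[-k], X_unlab, rfe_cfg,
          trainer = trainer, train_cfg = train_cfg),
      error = function(e) NULL)
    if (is.null(res)) {
      models[[k]] <- NULL
      selections[[k]] <- integer(0)
      sc <- NA_real_
    } else {
      sel <- res$final_features
      selections[[k]] <- sel
      m <- res$final_model
      w_full <- numeric(p)
      w_full[sel] <- m$w
      m$w <- w_full
      m$features <- colnames(X_lab)
      models[[k]] <- m
      sc <- decision_scores(m, X_lab[k, , drop = FALSE])
    }
    rows[[k]] <- tibble::tibble(
      fold = k, subject = rownames(X_lab)[k] %||% as.character(k),
      y_true = y_lab[k], score = sc,
      predicted = if (is.na(sc)) NA_integer_ else
        ifelse(sc >= train_cfg$delta, 1L, -1L),
      converged = !is.null(res))
  }
  folds <- dplyr::bind_rows(rows)
  ok <- folds$converged
  agg <- metrics(folds$y_true[ok], folds$score[ok], delta = train_cfg$delta,
                 outcome_sums = outcome_sums[ok])
  agg$partial <- any(!ok)
  new_cv_result(folds, models, agg, trainer, train_cfg,
                extra = list(selections = selections))
}

#' Run one end-to-end experiment
#'
#' Data, labels, features, model, evaluation and stability in one call,
#' with every artifact written to `cfg$out_dir`: the feature matrix and
#' dictionary, per-fold cross-validation results, a one-row metrics table
#' (sensitivity/specificity/accuracy as percentages alongside AUC, Pcorr,
#' Scorr), a stability report, the blind-test fraction on the control
#' cohort, and a provenance manifest (config hash, seed, package version).
#' Identical configurations produce identical artifacts.
#'
#' @param cfg An [experiment_config()] with a non-`NULL` `out_dir`.
#' @return Invisibly, a list with the in-memory results (`cv`, `stability`,
#'   `metrics_row`, `blind_fraction`, `data`, `paths`).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"), !is.null(cfg$out_dir))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- prepare_experiment_data(cfg)
  train_cfg <- training_config(r = cfg$r)
  trainer <- cfg$model

  cv <- if (!is.null(cfg$rfe)) {
    loocv_with_rfe(dat$X_lab, dat$y_lab,
                   if (trainer == "semisupervised") dat$X_unlab else NULL,
                   train_cfg, cfg$rfe, trainer, dat$outcome_sums)
  } else if (!is.null(cfg$r_grid) && trainer == "semisupervised") {
    nested_loocv(dat$X_lab, dat$y_lab, dat$X_unlab, cfg$r_grid, train_cfg,
                 outcome_sums = dat$outcome_sums)
  } else {
    loocv(dat$X_lab, dat$y_lab,
          if (trainer == "semisupervised") dat$X_unlab else NULL,
          train_cfg, trainer = trainer, outcome_sums = dat$outcome_sums)
  }

  ok_models <- purrr::compact(cv$models)
  stab <- if (length(ok_models) >= 2) fold_stability(ok_models) else NULL

  final_model <- fit_trainer(trainer, dat$X_lab, dat$y_lab,
                             if (trainer == "semisupervised") dat$X_unlab
                             else NULL, train_cfg)
  blind <- blind_test(final_model, dat$X_controls)

  metrics_row <- tibble::tibble(
    feature_type = cfg$feature_type,
    contrast = paste(cfg$contrasts, collapse = "+"),
    model = trainer, n_features = dat$n_features,
    sensitivity_pct = 100 * cv$metrics$sensitivity,
    specificity_pct = 100 * cv$metrics$specificity,
    accuracy_pct = 100 * cv$metrics$accuracy,
    auc = cv$metrics$auc, pcorr = cv$metrics$pcorr,
    scorr = cv$metrics$scorr)

  paths <- list(
    features = file.path(cfg$out_dir, "features.csv"),
    labels = file.path(cfg$out_dir, "labels.csv"),
    cv_folds = file.path(cfg$out_dir, "cv_folds.csv"),
    metrics = file.path(cfg$out_dir, "metrics.csv"),
    stability = file.path(cfg$out_dir, "stability.json"),
    manifest = file.path(cfg$out_dir, "manifest.json"))
  allX <- rbind(dat$X_lab, dat$X_unlab, dat$X_controls)
  readr::write_csv(dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(allX)),
    tibble::as_tibble(as.data.frame(allX))), paths$features)
  corr <- score_correlations(dat$score_table)
  readr::write_csv(tidy(corr), file.path(cfg$out_dir, "correlations.csv"))
  readr::write_csv(tibble::tibble(participant = dat$labels$participant,
                                  label = dat$labels$label), paths$labels)
  readr::write_csv(cv$folds, paths$cv_folds)
  readr::write_csv(metrics_row, paths$metrics)
  if (!is.null(stab)) {
    jsonlite::write_json(
      list(bias_std = stab$bias_std,
           median_distance = median(stab$pairwise$distance),
           distances = stab$pairwise$distance),
      paths$stability, auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(dat$dictionaries)) {
    if (!is.null(dat$dictionaries[[nm]])) {
      write_dictionary(dat$dictionaries[[nm]],
                       file.path(cfg$out_dir, paste0("dictionary_", nm,
                                                     ".json")))
    }
  }
  jsonlite::write_json(
    list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
         package_version = as.character(utils::packageVersion("bowsvm")),
         blind_test_fraction = blind),
    paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(cv = cv, stability = stab, metrics_row = metrics_row,
                 blind_fraction = blind, final_model = final_model,
                 data = dat, paths = paths))
}

#' Sweep the RFE target feature count
#'
#' Evaluates a cross-validated model (with per-fold feature selection) at
#' each target count and reports the metric row plus a percentile-bootstrap
#' confidence interval for the AUC. Target counts of 1 are rejected: with a
#' single feature the margin problem is routinely infeasible.
#'
#' @param cfg An [experiment_config()].
#' @param target_counts Integer vector of final feature counts (all >= 2).
#' @param n_boot Bootstrap resamples for the AUC interval.
#' @return A tibble with one row per target count.
#' @export
sweep_rfe <- function(cfg, target_counts, n_boot = 1000L) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (any(target_counts < 2)) {
    stop_bowsvm("target counts must be >= 2 (training at 1 feature does not converge)",
                "bowsvm_config_error")
  }
  dat <- prepare_experiment_data(cfg)
  if (any(target_counts > dat$n_features)) {
    stop_bowsvm("target count exceeds the number of features",
                "bowsvm_config_error")
  }
  train_cfg <- training_config(r = cfg$r)
  rows <- lapply(target_counts, function(tc) {
    rc <- rfe_config(target_n_features = tc)
    cv <- loocv_with_rfe(dat$X_lab, dat$y_lab,
                         if (cfg$model == "semisupervised") dat$X_unlab
                         else NULL,
                         train_cfg, rc, cfg$model, dat$outcome_sums)
    ok <- cv$folds$converged
    ci <- bootstrap_auc_ci(cv$folds$y_true[ok], cv$folds$score[ok],
                           n_boot = n_boot,
                           seed = stage_seed(cfg$seed, 300L + tc))
    dplyr::bind_cols(tibble::tibble(n_selected = tc), cv$metrics,
                     tibble::tibble(auc_lower = ci["lower"],
                                    auc_upper = ci["upper"]))
  })
  dplyr::bind_rows(rows)
}
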