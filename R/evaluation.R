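#' AUC by the rank (Mann-Whitney) formulation
#'
#' Area under the ROC curve computed from ranks with half-credit for tied
#' scores; identical to counting concordant score pairs.
#'
#' @param y_true Labels in `{-1, +1}` (both classes required).
#' @param scores Decision scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y_true, scores) {
  pos <- y_true == 1L
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_bowsvm("AUC undefined: only one class present", "bowsvm_metric_error")
  }
  r <- rank(scores)  # average ranks give ties half credit
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

sens_spec_f <- function(y_true, pred) {
  tp <- sum(pred == 1L & y_true == 1L)
  fn <- sum(pred == -1L & y_true == 1L)
  tn <- sum(pred == -1L & y_true == -1L)
  fp <- sum(pred == 1L & y_true == -1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f <- if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(y_true), f_measure = f)
}

#' Classification metrics from held-out decision scores
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, the
#' F-measure as the harmonic mean of sensitivity and specificity
#' (`2 * sens * spec / (sens + spec)`, 0 when both are 0), AUC by the rank
#' formulation, and — when outcome sums are supplied — the Pearson and
#' Spearman correlations between the scores and the outcome sums.
#'
#' @param y_true Labels in `{-1, +1}`.
#' @param scores Decision scores, one per sample.
#' @param delta Decision threshold (predict +1 when `score >= delta`).
#' @param outcome_sums Optional outcome-score sums for the correlation
#'   metrics.
#' @return A one-row tibble (a `MetricsBundle`).
#' @export
metrics <- function(y_true, scores, delta = 0, outcome_sums = NULL) {
  y_true <- as.integer(y_true)
  pred <- ifelse(scores >= delta, 1L, -1L)
  base <- sens_spec_f(y_true, pred)
  tibble::tibble(
    n = length(y_true),
    sensitivity = base$sensitivity, specificity = base$specificity,
    accuracy = base$accuracy, f_measure = base$f_measure,
    auc = auc_rank(y_true, scores),
    pcorr = if (is.null(outcome_sums)) NA_real_ else
      cor(scores, outcome_sums, method = "pearson"),
    scorr = if (is.null(outcome_sums)) NA_real_ else
      cor(scores, outcome_sums, method = "spearman"))
}

#' ROC curve points
#'
#' @inheritParams auc_rank
#' @return A tibble with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the endpoints.
#' @export
roc_points <- function(y_true, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  rows <- lapply(thr, function(t) {
    pred <- ifelse(scores >= t, 1L, -1L)
    tibble::tibble(threshold = t,
                   fpr = sum(pred == 1L & y_true == -1L) / sum(y_true == -1L),
                   tpr = sum(pred == 1L & y_true == 1L) / sum(y_true == 1L))
  })
  dplyr::bind_rows(rows)
}

new_cv_result <- function(folds, models, metrics, trainer, config,
                          extra = list()) {
  structure(c(list(folds = folds, models = models, metrics = metrics,
                   trainer = trainer, config = config), extra),
            class = "cv_result")
}

#' Leave-one-out cross-validation
#'
#' One fold per labeled sample, in row order: the held-out sample is scored
#' by a model trained on the remaining labeled samples (plus, in
#' semi-supervised mode, all unlabeled samples — unlabeled samples are used
#' only for training, never tested). Aggregate metrics are computed from
#' the held-out scores accumulated across folds. Folds whose training
#' fails are recorded as unconverged and excluded from the aggregate, which
#' is then marked partial.
#'
#' @param X_lab Labeled feature matrix (>= 2 samples per class).
#' @param y_lab Labels in `{-1, +1}`.
#' @param X_unlab Optional unlabeled feature rows.
#' @param cfg A [training_config()].
#' @param trainer `"supervised"` or `"semisupervised"`.
#' @param outcome_sums Optional per-sample outcome sums for Pcorr/Scorr.
#' @return A `cv_result`: `folds` tibble (per-fold held-out score and
#'   prediction), `models` (per-fold fitted models), `metrics` (aggregate
#'   [metrics()] row).
#' @export
loocv <- function(X_lab, y_lab, X_unlab = NULL, cfg = training_config(),
                  trainer = c("supervised", "semisupervised"),
                  outcome_sums = NULL) {
  trainer <- match.arg(trainer)
  X_lab <- as_feature_matrix(X_lab)
  y_lab <- check_labels(y_lab)
  if (min(table(y_lab)) < 2) {
    stop_bowsvm("need at least 2 labeled samples per class for LOOCV",
                "bowsvm_validation_error")
  }
  M <- nrow(X_lab)
  models <- vector("list", M)
  rows <- vector("list", M)
  for (k in seq_len(M)) {
    fit <- tryCatch(
      fit_trainer(trainer, X_lab[-k, , drop = FALSE], y_lab[-k], X_unlab, cfg),
      error = function(e) NULL)
    models[[k]] <- fit
    sc <- if (is.null(fit)) NA_real_ else
      decision_scores(fit, X_lab[k, , drop = FALSE])
    rows[[k]] <- tibble::tibble(
      fold = k, subject = rownames(X_lab)[k] %||% as.character(k),
      y_true = y_lab[k], score = sc,
      predicted = if (is.na(sc)) NA_integer_ else
        ifelse(sc >= cfg$delta, 1L, -1L),
      converged = !is.null(fit))
  }
  folds <- dplyr::bind_rows(rows)
  ok <- folds$converged
  agg <- metrics(folds$y_true[ok], folds$score[ok], delta = cfg$delta,
                 outcome_sums = outcome_sums[ok])
  agg$partial <- any(!ok)
  new_cv_result(folds, models, agg, trainer, cfg)
}

select_r <- function(f_by_r, r_grid, pos_fraction) {
  best_f <- max(f_by_r)
  tied <- which(f_by_r >= best_f - 1e-12)
  # ties: prefer the r closest to the labeled positive fraction, then smaller
  tied <- tied[order(abs(r_grid[tied] - pos_fraction), r_grid[tied])]
  tied[1]
}

#' Nested leave-one-out cross-validation with inner selection of r
#'
#' The outer LOOCV evaluates the model; the inner LOOCV (over the remaining
#' labeled samples, with the unlabeled samples always in the training side)
#' selects the positive-fraction parameter `r` from `r_grid` by maximizing
#' the inner F-measure. Ties are broken toward the `r` closest to the
#' labeled positive fraction, then toward smaller `r`. With a singleton
#' grid the procedure reduces exactly to [loocv()] at that `r`.
#'
#' @inheritParams loocv
#' @param r_grid Candidate positive fractions (default 0 to 1 by 0.1 — the
#'   11-value grid).
#' @return A `cv_result` whose `folds` tibble carries the per-fold selected
#'   `r`.
#' @export
nested_loocv <- function(X_lab, y_lab, X_unlab, r_grid = seq(0, 1, by = 0.1),
                         cfg = training_config(), outcome_sums = NULL) {
  if (length(r_grid) == 0) {
    stop_bowsvm("r_grid must be non-empty", "bowsvm_config_error")
  }
  X_lab <- as_feature_matrix(X_lab)
  y_lab <- check_labels(y_lab)
  M <- nrow(X_lab)
  models <- vector("list", M)
  rows <- vector("list", M)
  for (k in seq_len(M)) {
    X_in <- X_lab[-k, , drop = FALSE]
    y_in <- y_lab[-k]
    if (length(r_grid) > 1) {
      f_by_r <- vapply(r_grid, function(r) {
        cfg_r <- cfg; cfg_r$r <- r
        inner <- loocv(X_in, y_in, X_unlab, cfg_r, trainer = "semisupervised")
        ok <- inner$folds$converged
        sens_spec_f(inner$folds$y_true[ok],
                    inner$folds$predicted[ok])$f_measure
      }, numeric(1))
      chosen <- r_grid[select_r(f_by_r, r_grid, mean(y_in == 1L))]
    } else {
      chosen <- r_grid[1]
    }
    cfg_k <- cfg; cfg_k$r <- chosen
    fit <- tryCatch(train_semisupervised(X_in, y_in, X_unlab, cfg_k),
                    error = function(e) NULL)
    models[[k]] <- fit
    sc <- if (is.null(fit)) NA_real_ else
      decision_scores(fit, X_lab[k, , drop = FALSE])
    rows[[k]] <- tibble::tibble(
      fold = k, subject = rownames(X_lab)[k] %||% as.character(k),
      y_true = y_lab[k], score = sc,
      predicted = if (is.na(sc)) NA_integer_ else
        ifelse(sc >= cfg$delta, 1L, -1L),
      r_selected = chosen, converged = !is.null(fit))
  }
  folds <- dplyr::bind_rows(rows)
  ok <- folds$converged
  agg <- metrics(folds$y_true[ok], folds$score[ok], delta = cfg$delta,
                 outcome_sums = outcome_sums[ok])
  agg$partial <- any(!ok)
  new_cv_result(folds, models, agg, "semisupervised", cfg,
                extra = list(r_grid = r_grid))
}

#' Add unlabeled samples to the training set one by one
#'
#' For each prefix of the given ordering of the unlabeled samples, sets `r`
#' to the fraction of reference-positive samples within the prefix (the
#' reference labels come from a full-data semi-supervised fit) and
#' evaluates a semi-supervised LOOCV with just that prefix as the unlabeled
#' set.
#'
#' @inheritParams loocv
#' @param order Permutation of the unlabeled sample indices.
#' @param reference_labels Labels (+1/-1) for the unlabeled samples from a
#'   full-data semi-supervised fit.
#' @return A tibble with one row per prefix size: `n_added`,
#'   `sample_index`, `label`, `r_used` and the aggregate metric columns.
#' @export
add_unlabeled_incrementally <- function(X_lab, y_lab, X_unlab,
                                        order = seq_len(nrow(X_unlab)),
                                        reference_labels,
                                        cfg = training_config(),
                                        outcome_sums = NULL) {
  X_unlab <- as_feature_matrix(X_unlab)
  stopifnot(length(reference_labels) == nrow(X_unlab),
            setequal(order, seq_len(nrow(X_unlab))))
  rows <- lapply(seq_along(order), function(p) {
    idx <- order[seq_len(p)]
    r_used <- mean(reference_labels[idx] == 1L)
    cfg_p <- cfg; cfg_p$r <- r_used
    res <- loocv(X_lab, y_lab, X_unlab[idx, , drop = FALSE], cfg_p,
                 trainer = "semisupervised", outcome_sums = outcome_sums)
    dplyr::bind_cols(
      tibble::tibble(n_added = p, sample_index = order[p],
                     label = reference_labels[order[p]], r_used = r_used),
      res$metrics)
  })
  dplyr::bind_rows(rows)
}

#' Blind test: fraction of a holdout cohort classified as expected
#'
#' Applies a trained model to holdout rows (e.g. normal-hearing controls,
#' all of whom should be classified effective) and reports the fraction
#' predicted as `expected_label`.
#'
#' @param model A `bow_svm`.
#' @param X_holdout Holdout feature rows (>= 1).
#' @param expected_label The label every holdout row should receive.
#' @return Fraction in `[0, 1]`.
#' @export
blind_test <- function(model, X_holdout, expected_label = 1L) {
  if (NROW(X_holdout) == 0) {
    stop_bowsvm("empty holdout set: fraction undefined",
                "bowsvm_validation_error")
  }
  mean(classify(model, X_holdout) == expected_label)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' @inheritParams auc_rank
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(y_true, scores, n_boot = 1000L, conf = 0.95,
                             seed = 1L) {
  set.seed(seed)
  n <- length(y_true)
  vals <- replicate(n_boot, {
    idx <- sample(n, n, replace = TRUE)
    if (length(unique(y_true[idx])) < 2) NA_real_
    else auc_rank(y_true[idx], scores[idx])
  })
  q <- quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  setNames(as.numeric(q), c("lower", "upper"))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$trainer, "LOOCV |", nrow(x$folds), "folds\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) x$metrics

#' @export
autoplot.cv_result <- function(object, ...) {
  ok <- object$folds$converged
  pts <- roc_points(object$folds$y_true[ok], object$folds$score[ok])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("%s LOOCV ROC (AUC = %.2f)", object$trainer,
                      object$metrics$auc)) +
    ggplot2::theme_minimal()
}
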