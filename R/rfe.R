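#' Recursive feature elimination settings
#'
#' @param drop_fraction Fraction of remaining features removed per iteration
#'   (in `(0, 1)`); the count removed is `floor(drop_fraction * n)` with a
#'   floor of 1.
#' @param small_set_threshold When fewer than this many features remain,
#'   exactly one feature is removed per iteration.
#' @param target_n_features Number of surviving features to stop at (>= 1).
#' @return An `rfe_config` list.
#' @export
rfe_config <- function(drop_fraction = 0.01, small_set_threshold = 100L,
                       target_n_features = 2L) {
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop_bowsvm("drop_fraction must lie in (0, 1)", "bowsvm_config_error")
  }
  if (target_n_features < 1) {
    stop_bowsvm("target_n_features must be >= 1", "bowsvm_config_error")
  }
  structure(list(drop_fraction = drop_fraction,
                 small_set_threshold = as.integer(small_set_threshold),
                 target_n_features = as.integer(target_n_features)),
            class = "rfe_config")
}

# the elimination schedule is a pure function of the surviving count
n_to_remove <- function(n, cfg) {
  n_rm <- if (n < cfg$small_set_threshold) 1L
          else max(1L, as.integer(floor(cfg$drop_fraction * n)))
  as.integer(min(n_rm, n - cfg$target_n_features))
}

#' Recursive feature elimination over either model type
#'
#' Repeatedly trains a model on the surviving features, ranks features by
#' the absolute weight `|w_j|`, and removes the lowest-ranked ones (1% of
#' the survivors per iteration by default, one at a time once fewer than
#' 100 remain) until the target count is reached. Ties in `|w|` are broken
#' deterministically: the higher feature id is removed first.
#'
#' @param X Labeled feature matrix. @param y Labels in `{-1, +1}`.
#' @param X_unlab Optional unlabeled rows (used at every elimination step
#'   when the trainer is semi-supervised).
#' @param cfg An [rfe_config()].
#' @param trainer `"supervised"` or `"semisupervised"`.
#' @param train_cfg A [training_config()].
#' @return An `rfe_result`: `trace` (tibble of per-iteration eliminations,
#'   with removed ids in a list column), `final_features` (surviving
#'   original column ids), `final_model`.
#' @export
rfe <- function(X, y, X_unlab = NULL, cfg = rfe_config(),
                trainer = c("supervised", "semisupervised"),
                train_cfg = training_config()) {
  trainer <- match.arg(trainer)
  X <- as_feature_matrix(X)
  if (cfg$target_n_features > ncol(X)) {
    stop_bowsvm("target_n_features exceeds the number of features",
                "bowsvm_config_error")
  }
  surviving <- seq_len(ncol(X))
  trace <- list()
  it <- 0L
  model <- NULL
  repeat {
    it <- it + 1L
    model <- tryCatch(
      fit_trainer(trainer, X[, surviving, drop = FALSE], y,
                  if (is.null(X_unlab)) NULL else
                    X_unlab[, surviving, drop = FALSE],
                  train_cfg),
      error = function(e) {
        stop_bowsvm(sprintf("training failed at RFE iteration %d (%d features): %s",
                            it, length(surviving), conditionMessage(e)),
                    "bowsvm_training_error")
      })
    if (length(surviving) <= cfg$target_n_features) break
    n_rm <- n_to_remove(length(surviving), cfg)
    aw <- abs(model$w)
    # lowest |w| first; among ties the higher original id goes first
    ord <- order(aw, -surviving)
    removed <- surviving[ord[seq_len(n_rm)]]
    trace[[it]] <- tibble::tibble(iteration = it,
                                  n_before = length(surviving),
                                  removed = list(sort(removed)))
    surviving <- setdiff(surviving, removed)
  }
  structure(list(trace = dplyr::bind_rows(trace),
                 final_features = surviving, final_model = model,
                 config = cfg, trainer = trainer),
            class = "rfe_result")
}

fit_trainer <- function(trainer, X, y, X_unlab, train_cfg) {
  if (trainer == "semisupervised") {
    train_semisupervised(X, y, X_unlab, train_cfg)
  } else {
    train_supervised(X, y, train_cfg)
  }
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result>", x$trainer, "RFE:",
      if (nrow(x$trace)) x$trace$n_before[1] else length(x$final_features),
      "->", length(x$final_features), "features in", nrow(x$trace),
      "iterations\n")
  invisible(x)
}

#' @export
tidy.rfe_result <- function(x, ...) x$trace

#' Random feature-pair baseline
#'
#' Draws `n_trials` random pairs of features and evaluates a leave-one-out
#' cross-validated model on each pair, recording the AUC. Pairs on which
#' training fails to converge are recorded as failures, not raised — with
#' arbitrary feature pairs the two groups need not be separable. The
#' resulting AUC distribution is the null against which an RFE-selected
#' pair is compared.
#'
#' @inheritParams rfe
#' @param n_trials Number of random pairs (0 gives an empty result).
#' @param seed Integer seed for the pair draws.
#' @return A tibble with `trial`, `feature_1`, `feature_2`, `auc`,
#'   `converged`.
#' @export
random_pair_baseline <- function(X, y, X_unlab = NULL, n_trials = 100L,
                                 seed = 1L,
                                 trainer = c("semisupervised", "supervised"),
                                 train_cfg = training_config()) {
  trainer <- match.arg(trainer)
  X <- as_feature_matrix(X)
  if (ncol(X) < 2) stop_bowsvm("need at least 2 features", "bowsvm_config_error")
  set.seed(seed)
  pairs <- lapply(seq_len(n_trials), function(i) sort(sample(ncol(X), 2L)))
  rows <- purrr::map2(pairs, seq_along(pairs), function(p, i) {
    res <- tryCatch(
      loocv(X[, p, drop = FALSE], y,
            if (is.null(X_unlab)) NULL else X_unlab[, p, drop = FALSE],
            trainer = trainer, cfg = train_cfg),
      error = function(e) NULL)
    tibble::tibble(trial = i, feature_1 = p[1], feature_2 = p[2],
                   auc = if (is.null(res)) NA_real_ else res$metrics$auc,
                   converged = !is.null(res))
  })
  dplyr::bind_rows(rows)
}
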