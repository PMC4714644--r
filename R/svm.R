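#' Training configuration for the linear SVM models
#'
#' The supervised model minimizes `1/2 ||w||^2 + C * sum(xi_i)` subject to
#' `y_i (w X_i + b) >= 1 - xi_i`, `xi_i >= 0`. The semi-supervised
#' (transductive) model adds unlabeled samples with their own slack penalty
#' `U * sum(xi*_j)` and the constraint that a fraction `r` of the unlabeled
#' samples carries the positive label. Training anneals the unlabeled
#' penalty from `u_anneal_start` up to `U`, switching (+1, -1) pairs of
#' unlabeled labels whenever that lowers the objective.
#'
#' @param C Regularization weight for labeled samples (> 0). The default of
#'   1 is the method's standard operating point.
#' @param U Regularization weight for unlabeled samples; defaults to `C`.
#' @param r Fraction of unlabeled samples treated as positive, in `[0, 1]`.
#' @param delta Decision threshold: predict +1 when the score is `>= delta`.
#' @param u_anneal_start Initial unlabeled penalty (<= `U`).
#' @param u_anneal_factor Multiplicative annealing step (> 1).
#' @param max_switch_iters Cap on total accepted label switches.
#' @param standardize Standardize features (center/scale by training data)
#'   before training. Off by default: the method trains on raw features.
#' @param seed Integer seed, kept for interface completeness; the solver and
#'   the switching rule are fully deterministic and never draw random
#'   numbers.
#' @return A `training_config` list.
#' @export
training_config <- function(C = 1, U = C, r = 0.5, delta = 0,
                            u_anneal_start = 1e-5 * C, u_anneal_factor = 2,
                            max_switch_iters = 500L, standardize = FALSE,
                            seed = 1L) {
  if (C <= 0 || U <= 0) stop_bowsvm("C and U must be > 0", "bowsvm_config_error")
  if (r < 0 || r > 1) stop_bowsvm("r must lie in [0, 1]", "bowsvm_config_error")
  if (u_anneal_start > U) {
    stop_bowsvm("u_anneal_start must be <= U", "bowsvm_config_error")
  }
  if (u_anneal_factor <= 1) {
    stop_bowsvm("u_anneal_factor must be > 1", "bowsvm_config_error")
  }
  structure(list(C = C, U = U, r = r, delta = delta,
                 u_anneal_start = u_anneal_start,
                 u_anneal_factor = u_anneal_factor,
                 max_switch_iters = as.integer(max_switch_iters),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "training_config")
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    stop_bowsvm("feature rows must be finite", "bowsvm_validation_error")
  }
  X
}

check_labels <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) {
    stop_bowsvm("labels must be -1 or +1", "bowsvm_validation_error")
  }
  if (length(unique(y)) < 2) {
    stop_bowsvm("both classes must be present in the labeled set",
                "bowsvm_training_error")
  }
  y
}

# single weighted-slack solve given a precomputed Gram matrix; returns the
# pieces every caller needs (alpha, b, scores on the training rows)
solve_gram <- function(K, y, C_vec) {
  sol <- smo_solve(K, as.numeric(y), as.numeric(C_vec))
  coef <- sol$alpha * y
  scores <- drop(K %*% coef) + sol$b
  list(alpha = sol$alpha, b = sol$b, coef = coef, scores = scores,
       w_norm2 = drop(crossprod(coef, K %*% coef)),
       iterations = sol$iterations, dual_objective = sol$dual_objective)
}

new_bow_svm <- function(w, b, type, config, diagnostics, features,
                        unlabeled_labels = NULL) {
  structure(list(w = w, b = b, type = type, config = config,
                 diagnostics = diagnostics, features = features,
                 unlabeled_labels = unlabeled_labels),
            class = "bow_svm")
}

#' Evaluate the supervised SVM objective
#'
#' `1/2 ||w||^2 + C * sum(max(0, 1 - y (Xw + b)))` — the primal objective of
#' the soft-margin linear SVM at an arbitrary `(w, b)`.
#'
#' @param w Weight vector.
#' @param b Bias.
#' @param X Feature rows.
#' @param y Labels in `{-1, +1}`.
#' @param C Labeled regularization weight.
#' @return The objective value.
#' @export
objective_supervised <- function(w, b, X, y, C) {
  X <- as_feature_matrix(X)
  xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
  0.5 * sum(w^2) + C * sum(xi)
}

#' Evaluate the semi-supervised SVM objective
#'
#' Adds the unlabeled slack penalty `U * sum(max(0, 1 - y* (Xw + b)))` to
#' the supervised objective, where `y*` are the current unlabeled label
#' assignments.
#'
#' @inheritParams objective_supervised
#' @param X_unlab,y_unlab Unlabeled feature rows and their current labels.
#' @param U Unlabeled regularization weight.
#' @return The objective value.
#' @export
objective_semisupervised <- function(w, b, X, y, C, X_unlab, y_unlab, U) {
  X_unlab <- as_feature_matrix(X_unlab)
  xi_star <- pmax(0, 1 - y_unlab * (drop(X_unlab %*% w) + b))
  objective_supervised(w, b, X, y, C) + U * sum(xi_star)
}

#' Train the supervised linear SVM
#'
#' Solves the soft-margin linear SVM by sequential minimal optimization on
#' the dual, to near machine precision (the training objective matches an
#' independent quadratic-programming solution to well below 1e-6 on small
#' instances).
#'
#' @param X Feature matrix (rows = samples).
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param cfg A [training_config()].
#' @return A `bow_svm` model: weight vector `w`, bias `b`, and
#'   `diagnostics` (per-sample slacks `xi`, the objective at the solution,
#'   solver iterations).
#' @export
train_supervised <- function(X, y, cfg = training_config()) {
  X <- as_feature_matrix(X)
  y <- check_labels(y)
  stopifnot(nrow(X) == length(y))
  std <- standardizer(X, cfg$standardize)
  Xs <- std$apply(X)
  K <- tcrossprod(Xs)
  fit <- solve_gram(K, y, rep(cfg$C, length(y)))
  w <- drop(crossprod(Xs, fit$coef))
  xi <- pmax(0, 1 - y * fit$scores)
  obj <- 0.5 * fit$w_norm2 + cfg$C * sum(xi)
  w_out <- std$fold_in(w)
  new_bow_svm(w_out$w, fit$b + w_out$b_shift, "supervised", cfg,
              diagnostics = list(xi = xi, xi_star = numeric(0),
                                 objective = obj, switch_count = 0L,
                                 iterations = fit$iterations),
              features = colnames(X))
}

standardizer <- function(X, on) {
  if (!on) {
    return(list(apply = identity, fold_in = function(w)
      list(w = w, b_shift = 0)))
  }
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  list(apply = function(M) sweep(sweep(M, 2, mu), 2, sg, `/`),
       fold_in = function(w) {
         ws <- w / sg
         list(w = ws, b_shift = -sum(ws * mu))
       })
}

#' Initial label assignment for the unlabeled samples
#'
#' Scores the unlabeled rows with a trained model and assigns +1 to the
#' `round(K * r)` rows with the highest predicted scores (half-away-from-
#' zero rounding; ties in score broken by row order), -1 to the rest.
#'
#' @param model A `bow_svm`.
#' @param X_unlab Unlabeled feature rows.
#' @param r Positive fraction in `[0, 1]`.
#' @return Integer labels in `{-1, +1}`, one per unlabeled row.
#' @export
initial_unlabeled_assignment <- function(model, X_unlab, r) {
  if (r < 0 || r > 1) stop_bowsvm("r must lie in [0, 1]", "bowsvm_config_error")
  X_unlab <- as_feature_matrix(X_unlab)
  K <- nrow(X_unlab)
  n_pos <- as.integer(round_half_up(K * r))
  s <- decision_scores(model, X_unlab)
  ord <- order(-s)  # stable: ties keep row order
  labels <- rep(-1L, K)
  labels[ord[seq_len(n_pos)]] <- 1L
  labels
}

#' Train the semi-supervised (transductive) linear SVM
#'
#' Three-step training with annealed label switching:
#' 1. Train a supervised model on the labeled samples and assign the
#'    `round(K * r)` highest-scoring unlabeled samples to +1.
#' 2. With a temporary unlabeled penalty `U_tmp`, retrain on all samples;
#'    while some (+1, -1) pair of unlabeled samples has both slacks positive
#'    and summing above 2 (the switching rule, which guarantees the swap can
#'    lower the objective), switch the pair whose swap yields the maximal
#'    objective drop and retrain.
#' 3. Increase `U_tmp` by `u_anneal_factor` and repeat step 2 until
#'    `U_tmp >= U`.
#'
#' Pair switches preserve the positive count, so exactly `round(K * r)`
#' unlabeled samples carry +1 throughout; within each `U_tmp` stage every
#' accepted switch strictly decreases the objective. With no unlabeled
#' samples the result is identical to [train_supervised()].
#'
#' @param X_lab,y_lab Labeled feature rows and labels (both classes).
#' @param X_unlab Unlabeled feature rows (may have zero rows).
#' @param cfg A [training_config()]; `r`, `U` and the annealing schedule
#'   are taken from it.
#' @return A `bow_svm` with `type = "semisupervised"`, the final unlabeled
#'   labels in `$unlabeled_labels`, and `diagnostics` including both slack
#'   sets, the switch count and the per-step objective trace.
#' @export
train_semisupervised <- function(X_lab, y_lab, X_unlab, cfg = training_config()) {
  X_lab <- as_feature_matrix(X_lab)
  y_lab <- check_labels(y_lab)
  if (is.null(X_unlab) || NROW(X_unlab) == 0) {
    return(train_supervised(X_lab, y_lab, cfg))
  }
  X_unlab <- as_feature_matrix(X_unlab)
  if (ncol(X_unlab) != ncol(X_lab)) {
    stop_bowsvm("labeled and unlabeled features have different dimensions",
                "bowsvm_dimension_error")
  }
  M <- nrow(X_lab); K_n <- nrow(X_unlab)

  m0 <- train_supervised(X_lab, y_lab, cfg)
  y_u <- initial_unlabeled_assignment(m0, X_unlab, cfg$r)

  Xall <- rbind(X_lab, X_unlab)
  std <- standardizer(Xall, cfg$standardize)
  Xs <- std$apply(Xall)
  G <- tcrossprod(Xs)
  lab_idx <- seq_len(M); unl_idx <- M + seq_len(K_n)

  eval_fit <- function(y_u, U_tmp) {
    yy <- c(y_lab, y_u)
    fit <- solve_gram(G, yy, c(rep(cfg$C, M), rep(U_tmp, K_n)))
    xi <- pmax(0, 1 - yy * fit$scores)
    obj <- 0.5 * fit$w_norm2 + cfg$C * sum(xi[lab_idx]) +
      U_tmp * sum(xi[unl_idx])
    list(fit = fit, xi = xi, objective = obj)
  }

  switch_count <- 0L
  trace <- list()
  U_tmp <- min(cfg$u_anneal_start, cfg$U)
  repeat {
    cur <- eval_fit(y_u, U_tmp)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      U_tmp = U_tmp, event = "anneal", objective = cur$objective)
    repeat {
      xi_star <- cur$xi[unl_idx]
      pos <- which(y_u == 1L & xi_star > 1e-8)
      neg <- which(y_u == -1L & xi_star > 1e-8)
      cand <- expand.grid(i = pos, j = neg)
      if (nrow(cand) > 0) {
        cand <- cand[xi_star[cand$i] + xi_star[cand$j] > 2, , drop = FALSE]
      }
      if (nrow(cand) == 0) break
      trials <- lapply(seq_len(nrow(cand)), function(t) {
        y_try <- y_u
        y_try[cand$i[t]] <- -1L
        y_try[cand$j[t]] <- 1L
        list(y = y_try, res = eval_fit(y_try, U_tmp))
      })
      objs <- vapply(trials, function(t) t$res$objective, numeric(1))
      best <- which.min(objs)
      if (cur$objective - objs[best] <= 1e-10) break
      switch_count <- switch_count + 1L
      if (switch_count > cfg$max_switch_iters) {
        stop_bowsvm(
          sprintf(paste("label switching did not converge within %d switches",
                        "(U_tmp = %g, objective = %g)"),
                  cfg$max_switch_iters, U_tmp, cur$objective),
          "bowsvm_convergence_error")
      }
      y_u <- trials[[best]]$y
      cur <- trials[[best]]$res
      trace[[length(trace) + 1L]] <- tibble::tibble(
        U_tmp = U_tmp, event = "switch", objective = cur$objective)
    }
    if (U_tmp >= cfg$U) break
    U_tmp <- min(U_tmp * cfg$u_anneal_factor, cfg$U)
  }

  coef <- cur$fit$coef
  w <- drop(crossprod(Xs, coef))
  w_out <- std$fold_in(w)
  new_bow_svm(
    w_out$w, cur$fit$b + w_out$b_shift, "semisupervised", cfg,
    diagnostics = list(xi = cur$xi[lab_idx], xi_star = cur$xi[unl_idx],
                       objective = cur$objective,
                       switch_count = switch_count,
                       iterations = cur$fit$iterations,
                       objective_trace = dplyr::bind_rows(trace)),
    features = colnames(X_lab), unlabeled_labels = y_u)
}

#' Decision scores of a linear model
#'
#' `y_hat = w . x + b` per row.
#'
#' @param model A `bow_svm` (or any list with `w` and `b`).
#' @param X Feature rows with `ncol(X) == length(w)`.
#' @return Numeric vector of scores.
#' @export
decision_scores <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != length(model$w)) {
    stop_bowsvm(sprintf("feature dimension mismatch: model has %d, data %d",
                        length(model$w), ncol(X)), "bowsvm_dimension_error")
  }
  drop(X %*% model$w) + model$b
}

#' Classify rows with a linear model
#'
#' Predicts +1 when the decision score is at least `delta` (inclusive),
#' otherwise -1.
#'
#' @inheritParams decision_scores
#' @param delta Decision threshold; defaults to the model's configured
#'   threshold (0 unless changed).
#' @return Integer labels in `{-1, +1}`.
#' @export
classify <- function(model, X, delta = NULL) {
  delta <- delta %||% model$config$delta %||% 0
  s <- decision_scores(model, X)
  ifelse(s >= delta, 1L, -1L)
}

#' @export
print.bow_svm <- function(x, ...) {
  cat("<bow_svm>", x$type, "linear SVM |", length(x$w), "features | b =",
      signif(x$b, 4), "| objective =", signif(x$diagnostics$objective, 6),
      "\n")
  if (x$type == "semisupervised") {
    cat("  unlabeled: ", sum(x$unlabeled_labels == 1L), "positive /",
        sum(x$unlabeled_labels == -1L), "negative,",
        x$diagnostics$switch_count, "label switches\n")
  }
  invisible(x)
}

#' @export
tidy.bow_svm <- function(x, ...) {
  tibble::tibble(
    term = x$features %||% paste0("x", seq_along(x$w)),
    estimate = unname(x$w))
}

#' @export
glance.bow_svm <- function(x, ...) {
  tibble::tibble(type = x$type, n_features = length(x$w), bias = x$b,
                 objective = x$diagnostics$objective,
                 switch_count = x$diagnostics$switch_count)
}

#' Serialize a linear model to JSON
#'
#' @param model A `bow_svm`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(type = model$type, w = model$w, b = model$b,
         config = unclass(model$config),
         objective = model$diagnostics$objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a training set in the sparse `label index:value` dialect
#'
#' One line per sample: the label followed by `index:value` pairs for the
#' nonzero features — the training-file format of classic SVM command-line
#' tools.
#'
#' @param X Feature rows.
#' @param y Labels (+1/-1; `NA` or 0 for unlabeled).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_sparse_svm <- function(X, y, path) {
  X <- as_feature_matrix(X)
  y <- ifelse(is.na(y), 0L, as.integer(y))
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    paste(c(sprintf("%+d", y[i]),
            sprintf("%d:%.17g", nz, X[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
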