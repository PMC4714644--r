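#' Angular distance between two weight vectors
#'
#' `1 - cos(theta)` where `theta` is the angle between the vectors: 0 for
#' identical orientation, 1 for orthogonal, 2 for opposite. Scale-invariant
#' in either argument.
#'
#' @param w1,w2 Nonzero numeric vectors of equal length.
#' @return A scalar in `[0, 2]`.
#' @export
weight_distance <- function(w1, w2) {
  if (length(w1) != length(w2)) {
    stop_bowsvm("weight vectors have different lengths",
                "bowsvm_dimension_error")
  }
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) {
    stop_bowsvm("angle undefined for a zero weight vector",
                "bowsvm_degenerate_error")
  }
  d <- 1 - sum(w1 * w2) / (n1 * n2)
  min(max(d, 0), 2)
}

#' Stability of per-fold models
#'
#' Summarizes how much the cross-validation fold models agree: all
#' `M (M - 1) / 2` pairwise angular distances between the fold weight
#' vectors, the full distance matrix, and the standard deviation of the
#' per-fold biases (sample, n - 1 convention).
#'
#' @param models List of >= 2 fitted `bow_svm` models (or a numeric matrix
#'   with one weight vector per row and an optional `biases` attribute).
#' @return A `stability_report`: `pairwise` tibble (`fold_i`, `fold_j`,
#'   `distance`), `distance_matrix`, `bias_std`.
#' @export
fold_stability <- function(models) {
  if (is.list(models)) {
    W <- do.call(rbind, lapply(models, `[[`, "w"))
    biases <- vapply(models, `[[`, numeric(1), "b")
  } else {
    W <- models
    biases <- attr(models, "biases") %||% rep(NA_real_, nrow(W))
  }
  M <- nrow(W)
  if (M < 2) stop_bowsvm("need at least 2 models", "bowsvm_validation_error")
  norms <- sqrt(rowSums(W^2))
  if (any(norms == 0)) {
    stop_bowsvm("angle undefined for a zero weight vector",
                "bowsvm_degenerate_error")
  }
  Wn <- W / norms
  D <- 1 - tcrossprod(Wn)
  D <- pmin(pmax(D, 0), 2)
  diag(D) <- 0
  idx <- which(lower.tri(D), arr.ind = TRUE)
  pairwise <- tibble::tibble(fold_i = idx[, 2], fold_j = idx[, 1],
                             distance = D[idx])
  structure(list(pairwise = pairwise, distance_matrix = D,
                 bias_std = sd(biases)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", nrow(x$pairwise), "pairwise distances | median",
      signif(median(x$pairwise$distance), 3), "| bias std",
      signif(x$bias_std, 3), "\n")
  invisible(x)
}

#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairwise),
                 median_distance = median(x$pairwise$distance),
                 max_distance = max(x$pairwise$distance),
                 bias_std = x$bias_std)
}

#' @export
autoplot.stability_report <- function(object, ...) {
  D <- object$distance_matrix
  df <- tidyr::expand_grid(fold_i = seq_len(nrow(D)),
                           fold_j = seq_len(ncol(D)))
  df$distance <- D[cbind(df$fold_i, df$fold_j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_j, y = .data$fold_i,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "fold", y = "fold",
                  fill = expression(1 - cos(theta)),
                  title = "Pairwise weight-vector distances across folds") +
    ggplot2::theme_minimal()
}

# union-find over feature ids for the correlation merge
merge_groups <- function(ids, pairs) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[[as.character(max(a, b))]] <- min(a, b)
  }
  vapply(ids, find, numeric(1))
}

#' Selection frequency of features across folds
#'
#' Counts how often each feature was selected across the per-fold feature
#' selections. Features whose absolute pairwise correlation over the full
#' feature matrix reaches `corr_merge_threshold` are first merged into a
#' single identity (transitive closure over the threshold graph) — copies
#' of the same contrast region occur repeatedly in the vocabulary and are
#' selected interchangeably. Counts sum to folds x features-per-fold.
#'
#' @param selections List with one integer vector of selected feature ids
#'   per fold, or a list of `rfe_result`s.
#' @param feature_matrix Optional full feature matrix used for the
#'   correlation merge; with `NULL`, no merging occurs.
#' @param corr_merge_threshold Absolute-correlation threshold in `(0, 1]`.
#' @return A tibble with `representative` (smallest member id), `members`
#'   (list column) and `count`, ordered by decreasing count.
#' @export
selection_frequency <- function(selections, feature_matrix = NULL,
                                corr_merge_threshold = 0.99) {
  if (corr_merge_threshold <= 0 || corr_merge_threshold > 1) {
    stop_bowsvm("corr_merge_threshold must lie in (0, 1]",
                "bowsvm_config_error")
  }
  sel <- lapply(selections, function(s) {
    if (inherits(s, "rfe_result")) s$final_features else as.integer(s)
  })
  occurred <- sort(unique(unlist(sel)))
  group_of <- setNames(occurred, occurred)
  if (!is.null(feature_matrix) && length(occurred) > 1) {
    cm <- abs(cor(as_feature_matrix(feature_matrix)[, occurred, drop = FALSE]))
    hit <- which(cm >= corr_merge_threshold & upper.tri(cm), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pairs <- cbind(occurred[hit[, 1]], occurred[hit[, 2]])
      group_of <- setNames(merge_groups(occurred, pairs), occurred)
    }
  }
  counts <- table(vapply(unlist(sel), function(f)
    group_of[[as.character(f)]], numeric(1)))
  reps <- as.integer(names(counts))
  tibble::tibble(
    representative = reps,
    members = lapply(reps, function(r) occurred[group_of == r]),
    count = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$representative)
}
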