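#' Load an outcome-score table from CSV
#'
#' Reads a CSV of CELF-P2 standard scores with header
#' `participant,core,receptive,expressive,content,structure`, validates
#' every score against the instrument range `[45, 155]`, and recomputes the
#' row sums (sums in the file are never trusted).
#'
#' @param path Path to the CSV file.
#' @return A tibble with the five score columns plus an integer `sum`.
#' @seealso [celf_scores()] for the packaged score table.
#' @export
load_scores <- function(path) {
  if (!file.exists(path)) {
    stop_bowsvm(paste("file not found:", path), "bowsvm_parse_error")
  }
  tbl <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) stop_bowsvm(paste("parse error:", conditionMessage(e)),
                                    "bowsvm_parse_error")
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop_bowsvm(sprintf("malformed row %d: %s", prob$row[1], prob$expected[1]),
                "bowsvm_parse_error")
  }
  expected <- c("participant", score_columns())
  if (nrow(tbl) == 0 || !identical(names(tbl)[seq_along(expected)], expected)) {
    stop_bowsvm(paste("header must be", paste(expected, collapse = ",")),
                "bowsvm_parse_error")
  }
  tbl <- dplyr::select(tbl, dplyr::all_of(expected))
  validate_score_table(tbl)
}

#' Validate a score table and recompute sums
#'
#' @param tbl A data frame with `participant` and the five score columns.
#' @return The validated tibble with a recomputed integer `sum` column.
#' @export
validate_score_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  for (col in score_columns()) {
    v <- tbl[[col]]
    bad <- which(!is.finite(v) | v < 45 | v > 155)
    if (length(bad) > 0) {
      stop_bowsvm(
        sprintf("score `%s` out of instrument range [45, 155] in row %d",
                col, bad[1]),
        "bowsvm_validation_error")
    }
  }
  tbl$sum <- as.integer(rowSums(as.matrix(tbl[score_columns()])))
  tbl
}

#' The packaged outcome-score table
#'
#' The 16-recipient CELF-P2 follow-up score table used throughout the
#' package's worked examples.
#'
#' @return A validated score tibble (16 rows).
#' @export
celf_scores <- function() {
  load_scores(system.file("extdata", "celf_p2_scores.csv",
                          package = "bowsvm", mustWork = TRUE))
}

#' Pairwise correlations between the five outcome scores
#'
#' Computes the 5x5 Pearson and Spearman correlation matrices of the five
#' CELF-P2 scores.
#'
#' @param tbl A validated score table (>= 3 rows, non-constant columns).
#' @return An object of class `score_correlations`: a list with `pearson`
#'   and `spearman` matrices.
#' @export
score_correlations <- function(tbl) {
  m <- as.matrix(tbl[score_columns()])
  if (nrow(m) < 3) {
    stop_bowsvm("need at least 3 rows to estimate correlations",
                "bowsvm_correlation_error")
  }
  const <- score_columns()[apply(m, 2, function(v) diff(range(v)) == 0)]
  if (length(const) > 0) {
    stop_bowsvm(paste("correlation undefined: constant column",
                      const[1]), "bowsvm_correlation_error")
  }
  structure(list(pearson = cor(m, method = "pearson"),
                 spearman = cor(m, method = "spearman")),
            class = "score_correlations")
}

#' @export
print.score_correlations <- function(x, digits = 2, ...) {
  off <- function(m) m[upper.tri(m)]
  cat("<score_correlations> off-diagonal ranges (rounded to", digits,
      "decimals, half away from zero):\n")
  cat("  Pearson :", round_half_up(min(off(x$pearson)), digits), "to",
      round_half_up(max(off(x$pearson)), digits), "\n")
  cat("  Spearman:", round_half_up(min(off(x$spearman)), digits), "to",
      round_half_up(max(off(x$spearman)), digits), "\n")
  invisible(x)
}

#' @export
tidy.score_correlations <- function(x, ...) {
  long <- function(m, method) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    tibble::tibble(method = method,
                   score_1 = rownames(m)[idx[, 1]],
                   score_2 = colnames(m)[idx[, 2]],
                   estimate = m[idx])
  }
  dplyr::bind_rows(long(x$pearson, "pearson"), long(x$spearman, "spearman"))
}

#' Derive effective/ineffective labels by 2-means clustering
#'
#' Clusters the recipients into two groups with k-means (k = 2, best of
#' `n_restarts` starts) and labels the cluster with the higher mean score
#' sum as `+1` (effective), the other as `-1` (ineffective). By default the
#' clustering runs on the five-score vectors; `space = "sum"` clusters the
#' 1-D score sums instead. The five scores share one scale, so no
#' standardization is applied.
#'
#' @param tbl A validated score table.
#' @param n_restarts Number of random restarts (best total within-cluster
#'   sum of squares wins).
#' @param seed Integer seed for the restarts.
#' @param space `"scores"` (5-D score vectors) or `"sum"` (1-D sums).
#' @return A `label_assignment` tibble with `participant` and `label`
#'   (+1 / -1); cluster sizes are in `attr(, "cluster_sizes")`.
#' @export
kmeans_labels <- function(tbl, n_restarts = 50L, seed = 1L,
                          space = c("scores", "sum")) {
  space <- match.arg(space)
  m <- if (space == "sum") {
    matrix(as.numeric(tbl$sum), ncol = 1)
  } else {
    as.matrix(tbl[score_columns()])
  }
  distinct <- unique(m)
  if (nrow(distinct) < 2) {
    stop_bowsvm("fewer than 2 distinct score vectors: clustering degenerate",
                "bowsvm_degenerate_error")
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(max(1L, n_restarts))) {
    ctr <- distinct[sample(nrow(distinct), 2L), , drop = FALSE]
    fit <- tryCatch(kmeans(m, centers = ctr, iter.max = 100L),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  mean_sum <- tapply(tbl$sum, best$cluster, mean)
  pos_cluster <- as.integer(names(which.max(mean_sum)))
  label <- ifelse(best$cluster == pos_cluster, 1L, -1L)
  out <- tibble::tibble(participant = tbl$participant, label = label)
  attr(out, "cluster_sizes") <- c(effective = sum(label == 1L),
                                  ineffective = sum(label == -1L))
  class(out) <- c("label_assignment", class(out))
  out
}
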