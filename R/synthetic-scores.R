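#' Generate a synthetic outcome-score table
#'
#' Emulates a table of five correlated CELF-P2 standard scores per implant
#' recipient, with two well-separated planted clusters (effective /
#' ineffective users). Correlation between scores is induced by a
#' shared-factor construction: each subject draws one common factor plus
#' five independent factors, giving every score pair the same requested
#' correlation before clipping to the instrument range.
#'
#' @param n_effective,n_ineffective Subjects per planted cluster.
#' @param cluster_means List with elements `ineffective` and `effective`,
#'   each a 5-vector of mean scores; defaults emulate the printed cohort.
#' @param within_cluster_sd Per-score SD inside a cluster (instrument units).
#' @param inter_score_correlation Requested pairwise correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble with columns `participant`, `core`, `receptive`,
#'   `expressive`, `content`, `structure`, `sum`, and the planted cluster in
#'   `planted`. Scores are integers in `[45, 155]`.
#' @export
generate_outcome_table <- function(n_effective = 9L, n_ineffective = 7L,
                                   cluster_means = list(
                                     ineffective = c(48, 50, 50, 50, 51),
                                     effective = c(72, 68, 77, 75, 85)),
                                   within_cluster_sd = 5,
                                   inter_score_correlation = 0.9,
                                   seed = 1L) {
  rho <- inter_score_correlation
  if (rho < 0 || rho >= 1) {
    stop_bowsvm("`inter_score_correlation` must lie in [0, 1)",
                "bowsvm_sim_error")
  }
  if (within_cluster_sd < 0) {
    stop_bowsvm("`within_cluster_sd` must be >= 0", "bowsvm_sim_error")
  }
  mu_i <- cluster_means$ineffective
  mu_e <- cluster_means$effective
  stopifnot(length(mu_i) == 5L, length(mu_e) == 5L)
  # k-means must be able to recover the planted split: require the cluster
  # means to be separated in sum-space by > 4 SD of the score sum
  sd_sum <- within_cluster_sd * sqrt(5 + 20 * rho)
  if (abs(sum(mu_e) - sum(mu_i)) <= 4 * sd_sum) {
    stop_bowsvm(
      "cluster means too close: k-means cannot recover the planted split",
      "bowsvm_sim_error")
  }

  set.seed(seed)
  n <- n_ineffective + n_effective
  planted <- c(rep("ineffective", n_ineffective), rep("effective", n_effective))
  mu <- rbind(matrix(mu_i, n_ineffective, 5, byrow = TRUE),
              matrix(mu_e, n_effective, 5, byrow = TRUE))
  z_common <- rnorm(n)
  z_own <- matrix(rnorm(n * 5), n, 5)
  scores <- mu + within_cluster_sd *
    (sqrt(rho) * z_common + sqrt(1 - rho) * z_own)
  scores <- pmin(pmax(round_half_up(scores), 45), 155)
  colnames(scores) <- score_columns()

  tibble::as_tibble(as.data.frame(scores)) |>
    dplyr::mutate(participant = seq_len(n), .before = 1) |>
    dplyr::mutate(sum = as.integer(rowSums(scores)), planted = planted)
}

score_columns <- function() {
  c("core", "receptive", "expressive", "content", "structure")
}

#' Generate the 2-D toy dataset with a low-density satellite cluster
#'
#' Two linearly separable Gaussian clouds (positive and negative) plus a
#' sparse "satellite" cluster on the positive side, populated by only two
#' labeled points but also by unlabeled points. Leaving one satellite point
#' out starves the supervised trainer of that region, tilting its
#' hyperplane; the unlabeled satellite points keep the semi-supervised
#' hyperplane in place. Setting `satellite_amplitude = 0` collapses the
#' satellite into the main positive cloud, removing the density gap.
#'
#' @param n_pos,n_neg,n_unlabeled Counts (all > 0).
#' @param seed Integer seed.
#' @param satellite_amplitude Scale of the satellite offset (1 = default
#'   geometry, 0 = no satellite).
#' @return A tibble with `x1`, `x2`, `label` (+1 / -1 / `NA` for unlabeled)
#'   and the generating component in `latent`.
#' @export
generate_toy2d <- function(n_pos = 9L, n_neg = 7L, n_unlabeled = 7L,
                           seed = 1L, satellite_amplitude = 1) {
  if (n_pos <= 0 || n_neg <= 0 || n_unlabeled <= 0) {
    stop_bowsvm("all counts must be > 0", "bowsvm_config_error")
  }
  set.seed(seed)
  sdv <- 0.25
  neg_c <- c(-1.6, 0)
  pos_c <- c(1.6, 0)
  sat_c <- pos_c + satellite_amplitude * c(-3.6, 3.0)

  n_sat_lab <- min(2L, n_pos)
  n_unl_pos <- round_half_up(4 / 7 * n_unlabeled)
  n_unl_sat <- min(2L, n_unl_pos)

  draw <- function(n, ctr) {
    cbind(rnorm(n, ctr[1], sdv), rnorm(n, ctr[2], sdv))
  }
  pts <- rbind(draw(n_pos - n_sat_lab, pos_c), draw(n_sat_lab, sat_c),
               draw(n_neg, neg_c),
               draw(n_unl_pos - n_unl_sat, pos_c), draw(n_unl_sat, sat_c),
               draw(n_unlabeled - n_unl_pos, neg_c))
  latent <- c(rep("positive", n_pos - n_sat_lab),
              rep("satellite", n_sat_lab),
              rep("negative", n_neg),
              rep("positive", n_unl_pos - n_unl_sat),
              rep("satellite", n_unl_sat),
              rep("negative", n_unlabeled - n_unl_pos))
  label <- c(rep(1L, n_pos), rep(-1L, n_neg), rep(NA_integer_, n_unlabeled))
  tibble::tibble(x1 = pts[, 1], x2 = pts[, 2], label = label, latent = latent)
}

#' Simulate artificial unlabeled feature vectors
#'
#' Draws rows `x = m + alpha * s * z` with `z` i.i.d. standard normal:
#' white noise of strength `alpha` around a per-feature mean, scaled by the
#' per-feature standard deviation. This is how artificial unlabeled samples
#' are produced from a labeled group's empirical mean and SD.
#'
#' @param m Per-feature mean vector.
#' @param s Per-feature standard-deviation vector (elementwise >= 0), same
#'   length as `m`.
#' @param alpha Noise-strength scalar (>= 0).
#' @param n_samples Number of rows to draw.
#' @param seed Integer seed.
#' @return A numeric matrix with `n_samples` rows and `length(m)` columns.
#' @export
simulate_unlabeled <- function(m, s, alpha, n_samples, seed = 1L) {
  if (length(m) != length(s)) {
    stop_bowsvm("`m` and `s` must have the same length",
                "bowsvm_dimension_error")
  }
  if (any(s < 0) || alpha < 0) {
    stop_bowsvm("`s` must be elementwise >= 0 and `alpha` >= 0",
                "bowsvm_config_error")
  }
  set.seed(seed)
  z <- matrix(rnorm(n_samples * length(m)), n_samples, length(m))
  out <- matrix(m, n_samples, length(m), byrow = TRUE) +
    alpha * sweep(z, 2, s, `*`)
  colnames(out) <- names(m)
  out
}
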