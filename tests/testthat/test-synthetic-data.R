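test_that("cohort generator honors the noiseless limit and cohort sizes", {
  cfg <- map_sim_config(grid_shape = c(10, 10, 10), n_controls = 1,
                        n_effective = 1, n_ineffective = 1, n_unlabeled = 0,
                        region_centers = list(c(5, 5, 5)), region_radius = 2,
                        effect_effective = 3, noise_sd = 0,
                        smoothing_fwhm = 0, seed = 1)
  co <- generate_cohort_maps(cfg)
  eff_map <- co$maps$eff01
  expect_true(all(eff_map$values[co$regions[[1]]] == 3.0))
  outside <- setdiff(seq_len(1000), co$regions[[1]])
  expect_true(all(eff_map$values[outside] == 0))

  co_full <- generate_cohort_maps(map_sim_config(seed = 5))
  expect_length(co_full$maps, 44)
  expect_equal(unname(table(co_full$manifest$group)[c("control", "effective",
                                                      "ineffective", "unlabeled")]),
               c(21L, 9L, 7L, 7L), ignore_attr = TRUE)
})

test_that("generators are pure functions of their seed", {
  cfg <- tiny_map_config(seed = 11)
  expect_identical(generate_cohort_maps(cfg), generate_cohort_maps(cfg))
  expect_identical(generate_toy2d(seed = 4), generate_toy2d(seed = 4))
  expect_identical(generate_outcome_table(seed = 9),
                   generate_outcome_table(seed = 9))
  expect_false(identical(generate_toy2d(seed = 4), generate_toy2d(seed = 5)))
})

test_that("invalid map configs name the offending field", {
  expect_error(map_sim_config(region_radius = 0), "region_radius",
               class = "bowsvm_config_error")
  expect_error(map_sim_config(grid_shape = c(4, 24, 24)), "grid_shape",
               class = "bowsvm_config_error")
  expect_error(map_sim_config(region_centers = list(c(2, 12, 12))),
               "region_centers", class = "bowsvm_config_error")
  expect_error(map_sim_config(n_controls = -1), "n_controls",
               class = "bowsvm_config_error")
})

test_that("mean effective-ineffective map difference peaks inside planted regions", {
  for (s in 1:10) {
    co <- generate_cohort_maps(tiny_map_config(seed = s))
    man <- co$manifest
    eff <- Reduce(`+`, lapply(co$maps[man$group == "effective"],
                              `[[`, "values")) / sum(man$group == "effective")
    ineff <- Reduce(`+`, lapply(co$maps[man$group == "ineffective"],
                                `[[`, "values")) / sum(man$group == "ineffective")
    d <- abs(eff - ineff)
    expect_in(which.max(d), unlist(co$regions))
  }
})

test_that("outcome tables honor degenerate noise and the instrument range", {
  tbl <- generate_outcome_table(within_cluster_sd = 0, seed = 2)
  expect_true(all(tbl$core[tbl$planted == "ineffective"] == 48))
  expect_true(all(as.matrix(tbl[score_cols <- c("core", "receptive",
                                                "expressive", "content",
                                                "structure")]) ==
                    rbind(matrix(rep(c(48, 50, 50, 50, 51), each = 7), 7),
                          matrix(rep(c(72, 68, 77, 75, 85), each = 9), 9))))
  tbl2 <- generate_outcome_table(seed = 3)
  m <- as.matrix(tbl2[score_cols])
  expect_true(all(m >= 45 & m <= 155))
  expect_identical(tbl2$sum, as.integer(rowSums(m)))
  # generated tables always pass the score-table invariants
  expect_silent(validate_score_table(tbl2))
})

test_that("requested inter-score correlation is achieved at large n", {
  tbl <- generate_outcome_table(n_effective = 200, n_ineffective = 200,
                                inter_score_correlation = 0.9, seed = 7)
  cm <- cor(as.matrix(tbl[c("core", "receptive", "expressive", "content",
                            "structure")]))
  off <- cm[upper.tri(cm)]
  expect_true(all(off >= 0.8 & off <= 1.0))
})

test_that("k-means on generated sums recovers the planted split exactly", {
  tbl <- generate_outcome_table(seed = 13)
  split <- best_1d_split(tbl$sum)
  planted_eff_sums <- sort(tbl$sum[tbl$planted == "effective"])
  expect_identical(sort(split$upper), planted_eff_sums)
  la <- kmeans_labels(tbl, seed = 1)
  expect_identical(la$label == 1L, tbl$planted == "effective")
})

test_that("infeasible score simulations are rejected", {
  expect_error(generate_outcome_table(inter_score_correlation = 1.2),
               class = "bowsvm_sim_error")
  expect_error(generate_outcome_table(within_cluster_sd = 40),
               "k-means", class = "bowsvm_sim_error")
})

test_that("toy generator produces the documented composition", {
  toy <- generate_toy2d(n_pos = 9, n_neg = 7, n_unlabeled = 7, seed = 1)
  expect_identical(nrow(toy), 23L)
  expect_identical(sum(!is.na(toy$label)), 16L)
  expect_identical(sum(toy$label == 1L, na.rm = TRUE), 9L)
  expect_identical(sum(toy$label == -1L, na.rm = TRUE), 7L)
  expect_error(generate_toy2d(n_pos = 0), class = "bowsvm_config_error")
})

test_that("without a satellite cluster both models reach the same LOOCV AUC", {
  gaps <- vapply(1:20, function(s) {
    d <- toy_split(generate_toy2d(seed = s, satellite_amplitude = 0))
    a_sup <- loocv(d$X_lab, d$y_lab, trainer = "supervised")$metrics$auc
    a_semi <- loocv(d$X_lab, d$y_lab, d$X_unlab, training_config(r = 0.6),
                    trainer = "semisupervised")$metrics$auc
    abs(a_sup - a_semi)
  }, numeric(1))
  expect_true(all(gaps <= 0.05))
})

test_that("artificial unlabeled samples follow x = m + alpha * s * z", {
  m <- c(a = 1, b = -2, c = 0.5)
  s <- c(2, 1, 0.1)
  expect_true(all(simulate_unlabeled(m, s, alpha = 0, n_samples = 5) ==
                    matrix(m, 5, 3, byrow = TRUE)))
  expect_true(all(simulate_unlabeled(m, rep(0, 3), alpha = 1, 4) ==
                    matrix(m, 4, 3, byrow = TRUE)))
  big <- simulate_unlabeled(m, s, alpha = 0.1, n_samples = 10000, seed = 3)
  expect_equal(apply(big, 2, sd), 0.1 * s, tolerance = 0.1,
               ignore_attr = TRUE)
  expect_error(simulate_unlabeled(c(1, 2), c(1, 2, 3), 0.1, 5),
               class = "bowsvm_dimension_error")
})
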