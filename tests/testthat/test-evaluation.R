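test_that("metrics reproduce the harmonic-mean F and AUC endpoints", {
  y <- c(1L, 1L, -1L, -1L)
  perfect <- metrics(y, c(2, 1, -1, -2))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(metrics(y, -c(2, 1, -1, -2))$auc, 0)

  half <- metrics(c(1L, 1L, -1L), c(1, -1, -1))
  expect_equal(half$sensitivity, 0.5)
  expect_equal(half$specificity, 1.0)
  expect_equal(half$f_measure, 2 / 3, tolerance = 1e-4)

  allwrong <- metrics(y, c(-1, -1, 1, 1))
  expect_equal(allwrong$f_measure, 0)
  expect_error(auc_rank(rep(1L, 4), rnorm(4)), class = "bowsvm_metric_error")
})

test_that("rank AUC equals the concordant-pair-counting oracle", {
  pair_auc <- function(y, s) {
    pos <- s[y == 1L]; neg <- s[y == -1L]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
    total / (length(pos) * length(neg))
  }
  set.seed(21)
  for (i in 1:50) {
    n <- 30
    y <- sample(c(rep(1L, 15), rep(-1L, 15)))
    s <- sample(round(rnorm(n), 1))  # coarse scores force ties
    expect_equal(auc_rank(y, s), pair_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC and Scorr are invariant to strictly increasing transforms", {
  set.seed(4)
  y <- sample(c(rep(1L, 8), rep(-1L, 8)))
  s <- rnorm(16)
  sums <- sample(200:420, 16)
  a <- metrics(y, s, outcome_sums = sums)
  b <- metrics(y, exp(s) - 0.5, delta = exp(0) - 0.5, outcome_sums = sums)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$scorr, b$scorr, tolerance = 1e-12)
})

test_that("LOOCV holds out every labeled subject exactly once", {
  d <- toy_split(generate_toy2d(seed = 2))
  res <- loocv(d$X_lab, d$y_lab, trainer = "supervised")
  expect_identical(nrow(res$folds), 16L)
  expect_identical(res$folds$fold, 1:16)
  expect_false(res$metrics$partial)

  semi <- loocv(d$X_lab, d$y_lab, d$X_unlab, training_config(r = 0.6),
                trainer = "semisupervised")
  # each semi-supervised fold trains on 15 labeled + 7 unlabeled = 22
  expect_identical(length(semi$models[[1]]$diagnostics$xi) +
                     length(semi$models[[1]]$diagnostics$xi_star), 22L)
  expect_error(loocv(d$X_lab[c(1, 10), ], d$y_lab[c(1, 10)]),
               class = "bowsvm_validation_error")
})

test_that("trivially separable data reach AUC 1 in LOOCV", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20, 5), 10, 2), matrix(rnorm(20, -5), 10, 2))
  y <- c(rep(1L, 10), rep(-1L, 10))
  expect_equal(loocv(X, y, trainer = "supervised")$metrics$auc, 1)
})

test_that("the default nested grid has 11 values and 15 inner rounds", {
  expect_length(seq(0, 1, by = 0.1), 11)
  d <- toy_split(generate_toy2d(seed = 3))
  # count inner rounds indirectly: the inner LOOCV trains on M - 2 labeled
  res <- nested_loocv(d$X_lab, d$y_lab, d$X_unlab, r_grid = c(0.5, 0.6),
                      cfg = training_config())
  expect_identical(nrow(res$folds), 16L)
  expect_true(all(res$folds$r_selected %in% c(0.5, 0.6)))
})

test_that("a singleton grid reproduces plain LOOCV bit for bit", {
  d <- toy_split(generate_toy2d(seed = 8))
  plain <- loocv(d$X_lab, d$y_lab, d$X_unlab, training_config(r = 0.6),
                 trainer = "semisupervised")
  nested <- nested_loocv(d$X_lab, d$y_lab, d$X_unlab, r_grid = 0.6,
                         cfg = training_config(r = 0.6))
  expect_identical(plain$folds$score, nested$folds$score)
  expect_identical(plain$metrics$auc, nested$metrics$auc)
  expect_error(nested_loocv(d$X_lab, d$y_lab, d$X_unlab, r_grid = numeric(0)),
               class = "bowsvm_config_error")
})

test_that("incremental unlabeled addition tracks the reference ratio", {
  d <- toy_split(generate_toy2d(seed = 10))
  full <- train_semisupervised(d$X_lab, d$y_lab, d$X_unlab,
                               training_config(r = 0.6))
  ref <- full$unlabeled_labels
  ord <- c(which(ref == 1L)[1], which(ref == -1L)[1],
           setdiff(seq_along(ref), c(which(ref == 1L)[1],
                                     which(ref == -1L)[1])))
  inc <- add_unlabeled_incrementally(d$X_lab, d$y_lab, d$X_unlab,
                                     order = ord, reference_labels = ref,
                                     cfg = training_config())
  expect_equal(inc$r_used[1], 1.0)   # first added sample is reference-positive
  expect_equal(inc$r_used[2], 0.5)   # prefix {+, -}
  expect_identical(nrow(inc), 7L)
  # the full prefix equals plain semi-supervised LOOCV at the same r
  plain <- loocv(d$X_lab, d$y_lab, d$X_unlab,
                 training_config(r = mean(ref == 1L)),
                 trainer = "semisupervised")
  expect_equal(inc$auc[7], plain$metrics$auc, tolerance = 1e-12)
})

test_that("blind test reports the expected-label fraction", {
  all_pos <- list(w = c(0, 0), b = 1, config = training_config())
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(blind_test(all_pos, X), 1.0)
  expect_equal(blind_test(all_pos, X, expected_label = -1L), 0.0)
  expect_error(blind_test(all_pos, X[0, , drop = FALSE]),
               class = "bowsvm_validation_error")
})

test_that("ROC points and bootstrap intervals are well-formed", {
  set.seed(12)
  y <- sample(c(rep(1L, 10), rep(-1L, 10)))
  s <- rnorm(20) + 0.8 * y
  pts <- roc_points(y, s)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  ci <- bootstrap_auc_ci(y, s, n_boot = 200, seed = 5)
  expect_true(ci["lower"] <= auc_rank(y, s) && auc_rank(y, s) <= ci["upper"])
})
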