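test_that("the symmetric separable pair gives the margin-maximizing model", {
  m <- train_supervised(matrix(c(-1, 1), 2, 1), c(-1L, 1L),
                        training_config(C = 100))
  expect_equal(unname(m$w), 1, tolerance = 1e-10)
  expect_equal(m$b, 0, tolerance = 1e-10)
  expect_equal(decision_scores(m, matrix(0)), 0, tolerance = 1e-10)
})

test_that("separable problems reach zero slack in the hard-margin limit", {
  set.seed(3)
  X <- rbind(matrix(rnorm(10, 3), 5, 2), matrix(rnorm(10, -3), 5, 2))
  y <- c(rep(1L, 5), rep(-1L, 5))
  m <- train_supervised(X, y, training_config(C = 1e6))
  expect_true(all(m$diagnostics$xi < 1e-8))
})

test_that("training preconditions are enforced", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(train_supervised(X, rep(1L, 5)),
               class = "bowsvm_training_error")
  expect_error(train_supervised(X, c(1L, 2L, 1L, -1L, -1L)),
               class = "bowsvm_validation_error")
  m <- train_supervised(X, c(1L, 1L, 1L, -1L, -1L))
  expect_error(decision_scores(m, matrix(rnorm(9), 3, 3)),
               class = "bowsvm_dimension_error")
})

test_that("supervised objective matches the exact QP oracle", {
  set.seed(11)
  for (i in 1:10) {
    n <- 8
    X <- matrix(rnorm(2 * n), n, 2)
    y <- sample(c(rep(1, 4), rep(-1, 4)))
    C <- sample(c(0.1, 1, 10), 1)
    m <- train_supervised(X, as.integer(y), training_config(C = C))
    mine <- objective_supervised(m$w, m$b, X, y, C)
    expect_equal(mine, m$diagnostics$objective, tolerance = 1e-8)
    expect_equal(mine, qp_oracle_objective(X, y, C), tolerance = 1e-6)
  }
})

test_that("initial unlabeled assignment takes the top-scoring round(K r)", {
  m <- list(w = c(1), b = 0, config = training_config())
  X7 <- matrix(7:1, ncol = 1)
  lab <- initial_unlabeled_assignment(m, X7, r = 0.6)
  expect_identical(sum(lab == 1L), 4L)           # round(7 * 0.6) = 4
  expect_identical(lab, c(1L, 1L, 1L, 1L, -1L, -1L, -1L))
  expect_true(all(initial_unlabeled_assignment(m, X7, 0) == -1L))
  expect_true(all(initial_unlabeled_assignment(m, X7, 1) == 1L))
  X8 <- matrix(8:1, ncol = 1)
  lab8 <- initial_unlabeled_assignment(m, X8, 0.5)
  expect_identical(which(lab8 == 1L), 1:4)       # scores 8,7,6,5
})

test_that("semi-supervised training reduces to supervised when K = 0 or U -> 0", {
  set.seed(5)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(1L, -1L), 6)
  m_sup <- train_supervised(X, y)
  expect_identical(train_semisupervised(X, y, NULL)$w, m_sup$w)
  expect_identical(train_semisupervised(X, y, X[0, , drop = FALSE])$w, m_sup$w)

  for (i in 1:20) {
    set.seed(100 + i)
    Xl <- rbind(matrix(rnorm(12, 1.5), 6, 2), matrix(rnorm(12, -1.5), 6, 2))
    yl <- c(rep(1L, 6), rep(-1L, 6))
    Xu <- matrix(rnorm(10, 0, 2), 5, 2)
    sup <- train_supervised(Xl, yl)
    semi <- train_semisupervised(Xl, yl, Xu,
                                 training_config(U = 1e-9,
                                                 u_anneal_start = 1e-12,
                                                 r = 0.6))
    expect_lt(weight_distance(sup$w, semi$w), 1e-4)
  }
})

test_that("label switching conserves counts and decreases the objective", {
  for (s in 1:5) {
    d <- toy_split(generate_toy2d(seed = s))
    m <- train_semisupervised(d$X_lab, d$y_lab, d$X_unlab,
                              training_config(r = 0.6))
    expect_identical(sum(m$unlabeled_labels == 1L), 4L)  # round(7 * 0.6)
    tr <- m$diagnostics$objective_trace
    for (u in unique(tr$U_tmp)) {
      expect_true(all(diff(tr$objective[tr$U_tmp == u]) <= 1e-9))
    }
    # reported objective matches an independent evaluation of the final model
    expect_equal(m$diagnostics$objective,
                 objective_semisupervised(m$w, m$b, d$X_lab, d$y_lab, 1,
                                          d$X_unlab, m$unlabeled_labels, 1),
                 tolerance = 1e-6)
  }
})

test_that("classification thresholds are inclusive and scores linear", {
  m <- list(w = c(0, 0), b = 0.5, config = training_config())
  X <- matrix(rnorm(6), 3, 2)
  expect_identical(unname(decision_scores(m, X)), rep(0.5, 3))
  expect_true(all(classify(m, X, delta = 0.5) == 1L))  # score == delta -> +1
  expect_true(all(classify(m, X, delta = Inf) == -1L))
  expect_true(all(classify(m, X, delta = -Inf) == 1L))
  m2 <- list(w = c(2, -1), b = 0, config = training_config())
  expect_equal(decision_scores(m2, 3 * X), 3 * decision_scores(m2, X))
})

test_that("training configs validate their invariants", {
  expect_error(training_config(C = 0), class = "bowsvm_config_error")
  expect_error(training_config(r = 1.5), class = "bowsvm_config_error")
  expect_error(training_config(u_anneal_start = 2, U = 1),
               class = "bowsvm_config_error")
  expect_error(training_config(u_anneal_factor = 1),
               class = "bowsvm_config_error")
})

test_that("models round-trip through tidy/glance and the sparse exporter", {
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  colnames(X) <- c("w1", "w2")
  y <- rep(c(1L, -1L), 5)
  m <- train_supervised(X, y)
  td <- tidy(m)
  expect_identical(td$term, c("w1", "w2"))
  expect_identical(td$estimate, unname(m$w))
  expect_identical(glance(m)$n_features, 2L)

  path <- withr::local_tempfile(fileext = ".txt")
  write_sparse_svm(X, y, path)
  lines <- readLines(path)
  expect_length(lines, 10)
  expect_match(lines[1], "^[+-]1( \\d+:-?[0-9.eE+-]+)+$")
})
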