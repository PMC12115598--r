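test_that("class balancing undersamples the majority without replacement", {
  set.seed(1)
  X <- matrix(rnorm(415 * 4), 415)
  y <- c(rep(1, 21), rep(0, 394))
  b <- balance_classes(X, y, seed = 7)
  expect_equal(sum(b$y == 1), 21)
  expect_equal(sum(b$y == 0), 21)
  expect_equal(length(b$idx), length(unique(b$idx)))
  expect_true(all(which(y == 1) %in% b$idx))  # minority kept whole

  b2 <- balance_classes(X, y, seed = 7)
  expect_identical(b$idx, b2$idx)             # deterministic under seed

  # already balanced input is returned unchanged as a set
  yb <- rep(c(0, 1), each = 10)
  bb <- balance_classes(X[1:20, ], yb, seed = 3)
  expect_equal(sort(bb$idx), 1:20)

  expect_error(balance_classes(X, rep(1, 415), seed = 1), "both classes")
})

test_that("metrics implement the four confusion-matrix formulas", {
  expect_equal(unname(compute_metrics(5, 5, 0, 0)), c(1, 1, 1, 1))
  expect_equal(unname(compute_metrics(1, 1, 1, 1)), c(0.5, 0.5, 0.5, 0.5))
  m <- compute_metrics(0, 7, 0, 3)
  expect_equal(unname(m), c(0.7, 0, 0, 0))
  expect_error(compute_metrics(0, 0, 0, 0), "no evaluated samples")
  # generic identity: f1 is the harmonic mean of precision and recall
  m2 <- compute_metrics(8, 11, 3, 2)
  expect_equal(m2[["f1"]],
               2 * m2[["precision"]] * m2[["recall"]] /
                 (m2[["precision"]] + m2[["recall"]]))
})

test_that("stratified folds keep class proportions within one sample", {
  y <- c(rep(1, 21), rep(0, 21))
  for (s in 1:10) {
    fold <- stratified_folds(y, 5, seed = s)
    glob <- mean(y)
    for (k in 1:5) {
      in_k <- fold == k
      expect_lte(abs(mean(y[in_k]) - glob), 1 / sum(in_k) + 1e-12)
    }
  }
  expect_error(stratified_folds(c(1, 1, 0), 5, 1), "at least as many")
})

test_that("grid search returns the paired-CV argmax with smallest-C ties", {
  set.seed(10)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 5, 0), n / 2),
             matrix(rnorm(n / 2 * 5, 4), n / 2))
  y <- rep(c(0, 1), each = n / 2)
  gs <- grid_search_C(X, y, seed = 2)
  expect_gte(max(gs$scores), 0.99)         # separable data
  expect_equal(gs$best_C, as.numeric(names(gs$scores)[which.max(gs$scores)]))
  # all-tie on separable data resolves to the smallest C
  if (length(unique(round(gs$scores, 10))) == 1) expect_equal(gs$best_C, 0.01)
  expect_equal(grid_search_C(X, y, grid = 7, seed = 2)$best_C, 7)
})

test_that("repeated stratified CV yields folds x repeats metric sets", {
  set.seed(11)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 6, 0), n / 2),
             matrix(rnorm(n / 2 * 6, 4), n / 2))
  y <- rep(c(0, 1), each = n / 2)
  cv <- repeated_stratified_cv(X, y, folds = 5, repeats = 20, C = 0.1, seed = 5)
  expect_equal(nrow(cv$iterations), 100)
  expect_true(all(cv$iterations$tp + cv$iterations$tn +
                    cv$iterations$fp + cv$iterations$fn == 8))
  mets <- cv$iterations[c("accuracy", "precision", "recall", "f1")]
  expect_true(all(mets >= 0 & mets <= 1))
  expect_gt(mean(cv$iterations$f1), 0.95)  # strongly separated classes

  cv2 <- repeated_stratified_cv(X, y, folds = 5, repeats = 20, C = 0.1, seed = 5)
  expect_identical(cv$iterations, cv2$iterations)  # determinism

  expect_error(repeated_stratified_cv(X[1:6, ], y[c(1:3, 21:23)], folds = 5),
               "at least")
})

test_that("shuffled labels drive CV F1 to chance on balanced data", {
  set.seed(12)
  X <- matrix(rnorm(60 * 6), 60)
  y <- rep(c(0, 1), 30)
  set.seed(99); y <- sample(y)
  cv <- repeated_stratified_cv(X, y, folds = 5, repeats = 10, C = 1, seed = 8)
  expect_lt(abs(mean(cv$iterations$f1) - 0.5), 0.1)
})

test_that("per-behavior confusion rates follow the counts", {
  expect_equal(confusion_rate_pct(43, 17), 39.53, tolerance = 5e-3)
  expect_equal(confusion_rate_pct(186, 30), 16.13, tolerance = 5e-3)
  expect_equal(confusion_rate_pct(10, 0), 0)

  # a model that separates perfectly has all rates 0
  db <- small_db(seed = 6)
  d <- build_design_matrix(db, frame = "world")
  model <- cowmotion:::fit_linear_svm(d$X, d$y, C = 1)
  conf <- confusion_by_behavior(model, d$X, d$meta$behavior)
  expect_setequal(conf$behavior, setdiff(behaviors, "active_mounting"))
  expect_true(all(conf$rate_pct == 0))
  expect_equal(conf$rate_pct, 100 * conf$fp / conf$n)
})
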