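test_that("min-max scaling maps training features onto [-1, 1]", {
  tr <- cbind(a = c(0, 5, 10), b = c(2, 2, 2))
  pp <- preprocess(tr, unit_norm = FALSE)
  expect_equal(unname(pp$train[, "a"]), c(-1, 0, 1))
  expect_equal(unname(pp$train[, "b"]), c(0, 0, 0)) # constant -> 0

  # test data uses the training parameters and may leave the range
  pp2 <- preprocess(tr, test = cbind(a = 20, b = 2), unit_norm = FALSE)
  expect_equal(unname(pp2$test[1, "a"]), 3)

  # preprocessed training output of the default pipeline: affine part
  # within [-1,1] before normalization, unit (or zero) rows after
  set.seed(2)
  x <- matrix(rnorm(200), 40, 5)
  full <- preprocess(x)
  affine <- preprocess(x, unit_norm = FALSE)$train
  expect_true(all(affine >= -1 - 1e-12 & affine <= 1 + 1e-12))
  nrms <- sqrt(rowSums(full$train^2))
  expect_true(all(abs(nrms - 1) < 1e-12 | nrms == 0))
})

test_that("unit normalization rescales rows to length one", {
  pp <- preprocess(cbind(3, 4), params = list(mins = c(-1, -1), maxs = c(1, 1)))
  expect_equal(unname(pp$train[1, ]), c(0.6, 0.8))
})

test_that("micro-averaged F1 pools counts and equals binary accuracy", {
  expect_equal(micro_f1(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  expect_equal(micro_f1(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(micro_f1(logical(0), logical(0)))
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    gold <- sample(c(TRUE, FALSE), n, replace = TRUE)
    expect_equal(micro_f1(pred, gold), mean(pred == gold))
  }
})

test_that("Cohen's kappa matches hand arithmetic and edge conventions", {
  expect_equal(cohens_kappa(c(1, 1, 0), c(1, 1, 0)), 1)
  # 2x2 agreement table a=20 b=5 c=10 d=15: po=0.7, pe=0.5
  a <- rep(c("y", "y", "n", "n"), times = c(20, 5, 10, 15))
  b <- rep(c("y", "n", "y", "n"), times = c(20, 5, 10, 15))
  expect_equal(cohens_kappa(a, b), 0.4)
  # both raters constant and identical
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)
  # constant raters that always disagree: expected agreement 0, kappa 0
  expect_equal(cohens_kappa(rep(1, 5), rep(0, 5)), 0)
  # independent raters hover near zero
  set.seed(4)
  ra <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  rb <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(ra, rb)), 0.05)
})

test_that("Chernoff sample-size bound truncates as documented", {
  expect_identical(chernoff_sample_size(0.05, 0.05), 3024L)
  expect_identical(chernoff_sample_size(1, 0.05), 11L)
  # halving epsilon roughly quadruples n
  n1 <- chernoff_sample_size(0.1, 0.05)
  n2 <- chernoff_sample_size(0.05, 0.05)
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.5)
  expect_error(chernoff_sample_size(0, 0.05))
  expect_error(chernoff_sample_size(0.05, 1))
})

test_that("linear SVM separates blobs and learns a symmetric bias", {
  bl <- blobs(n = 60, seed = 6)
  pp <- preprocess(bl$x)
  m <- fit_linear_svm(pp$train, bl$y)
  expect_equal(mean(predict(m, pp$train) == bl$y), 1)
  expect_named(m$w, colnames(bl$x))

  # symmetric two-point problem: bias near zero
  x2 <- rbind(c(1, 0), c(-1, 0), c(1, 0), c(-1, 0))
  colnames(x2) <- c("u", "v")
  m2 <- fit_linear_svm(x2, c(TRUE, FALSE, TRUE, FALSE))
  expect_lt(abs(m2$b), 1e-6)
  expect_error(fit_linear_svm(x2, rep(TRUE, 4)))
})

test_that("feature ranking sorts by squared weight with name tie-breaks", {
  m <- structure(
    list(w = c(alpha = 3, beta = -4, gamma = 0), b = 0, cost = 1,
         positive_label = TRUE),
    class = "linear_svm"
  )
  rk <- rank_features(m, n = 10)
  expect_equal(rk$feature, c("beta", "alpha", "gamma"))
  expect_equal(rk$w2, c(16, 9, 0))
  expect_equal(nrow(rank_features(m, 2)), 2L)
  # ties break lexicographically
  m2 <- structure(list(w = c(b = 1, a = -1), b = 0, cost = 1,
                       positive_label = TRUE), class = "linear_svm")
  expect_equal(rank_features(m2)$feature, c("a", "b"))
})

test_that("a planted discriminative feature is recovered at rank one", {
  set.seed(9)
  n <- 200
  x <- cbind(signal = rnorm(n), matrix(rnorm(n * 5, sd = 1), n, 5))
  colnames(x)[-1] <- paste0("noise", 1:5)
  y <- x[, "signal"] > 0
  pp <- preprocess(x)
  m <- fit_linear_svm(pp$train, y)
  expect_equal(rank_features(m, 1)$feature, "signal")
})

test_that("cost selection prefers the smallest tied cost", {
  bl <- blobs(n = 80, seed = 10)
  pp <- preprocess(bl$x)
  sel <- select_c(pp$train, bl$y, folds = 4, seed = 3)
  expect_equal(sel$cost, 0.001) # separable: every C reaches F1 = 1
  expect_true(all(sel$results$micro_f1 == 1))
  expect_equal(select_c(pp$train, bl$y, grid = 0.5, folds = 4)$cost, 0.5)
})

test_that("cost selection recovers the regime planted in noisy data", {
  # many noise dimensions, weak signal: heavy regularization wins over a
  # hard-margin fit
  set.seed(21)
  n <- 120
  x <- cbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 30), n, 30))
  colnames(x) <- paste0("f", 1:32)
  y <- (x[, 1] + x[, 2] + rnorm(n, sd = 2)) > 0
  pp <- preprocess(x)
  sel <- select_c(pp$train, y, grid = c(0.01, 1000), folds = 5, seed = 2)
  expect_equal(sel$cost, 0.01)
})

test_that("classifier comparison follows the documented chi-squared design", {
  gold <- rep(c(TRUE, FALSE), 100)
  # identical predictions: statistic 0, not significant
  same <- compare_classifiers(gold, gold, gold)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # perfect vs. chance at n = 200: significant
  set.seed(13)
  chance <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  res <- compare_classifiers(gold, chance, gold)
  expect_true(res$significant)
  # tiny n, equal accuracy: not significant
  tiny <- compare_classifiers(c(TRUE, FALSE), c(FALSE, TRUE),
                              c(TRUE, TRUE))
  expect_false(tiny$significant)
  # degenerate: both perfect but not identical is impossible; both perfect
  # -> zero incorrect column handled via the identical branch or flagged
  res2 <- compare_classifiers(gold, gold, gold, method = "mcnemar")
  expect_equal(res2$p_value, 1)
})

test_that("stratified cross-validation pools held-out predictions", {
  bl <- blobs(n = 100, seed = 15)
  cv <- cross_validate(bl$x, bl$y, k = 5, seed = 1)
  expect_equal(cv$micro_f1, 1)
  expect_equal(sum(cv$confusion), 100)

  # constant features: the fit degenerates to one class, accuracy 1/2 on
  # balanced data
  xc <- matrix(1, 40, 3)
  colnames(xc) <- c("a", "b", "c")
  yc <- rep(c(TRUE, FALSE), 20)
  cvc <- cross_validate(xc, yc, k = 4, seed = 2)
  expect_equal(cvc$micro_f1, 0.5, tolerance = 0.051)

  # fixed seed reproduces exactly
  cv2 <- cross_validate(bl$x, bl$y, k = 5, seed = 1)
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("rule baselines read the character after the period", {
  sites <- make_sites("ca.", right_token = c("eines", "Level", "", "(C43.5)"))
  expect_equal(baseline_abbrev(sites), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(baseline_sentence(sites), c(FALSE, TRUE, FALSE, TRUE))
})
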