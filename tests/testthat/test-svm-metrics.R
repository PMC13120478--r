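test_that("the four kernel forms evaluate exactly as printed", {
  expect_equal(svm_kernel(c(1, 2), c(3, 4), svm_config("linear")), 11)
  expect_equal(svm_kernel(c(1, 1), c(1, 1),
                          svm_config("polynomial", gamma = 1, r = 0,
                                     degree = 2)), 4)
  expect_equal(svm_kernel(c(1, 2), c(1, 2), svm_config("rbf", gamma = 0.5)), 1)
  x <- c(0.3, -0.2); y <- c(0.1, 0.4)
  expect_equal(svm_kernel(x, y, svm_config("rbf", gamma = 2)),
               exp(-2 * sum((x - y)^2)))
  expect_equal(svm_kernel(x, y, svm_config("sigmoid", gamma = 1, r = 0.5)),
               tanh(sum(x * y) + 0.5))
  expect_error(svm_config("rbf", gamma = -1), "gamma")
  expect_error(svm_kernel(c(1, 2), c(1, 2, 3), svm_config("linear")),
               "equal length")
})

test_that("LOO grid search separates separable clouds and respects grid order", {
  set.seed(1)
  x <- matrix(c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1)), ncol = 1)
  y <- rep(c("healthy", "MS"), each = 4)
  gs <- loo_grid_search(x, y, list(svm_config("linear", C = 1)))
  expect_equal(gs$best_score, 1)
  expect_equal(gs$best_config$kernel, "linear")
  expect_equal(nrow(gs$report), 1L)

  # single-config grid returns that config
  one <- svm_config("rbf", gamma = 0.5, C = 2)
  gs1 <- loo_grid_search(x, y, list(one))
  expect_identical(gs1$best_config, one)

  # ties break toward the earlier grid entry
  grid <- list(svm_config("linear", C = 1), svm_config("linear", C = 1.0001))
  gs2 <- loo_grid_search(x, y, grid)
  expect_identical(gs2$best_config, grid[[1]])
})

test_that("LOO score is invariant to row permutation", {
  set.seed(2)
  x <- matrix(rnorm(20, mean = rep(c(0, 2), each = 10)), ncol = 2)
  y <- rep(c("healthy", "MS"), each = 5)
  grid <- list(svm_config("linear", C = 1), svm_config("rbf", gamma = 1, C = 1))
  s1 <- loo_grid_search(x, y, grid)$report$cv_score
  perm <- sample(nrow(x))
  s2 <- loo_grid_search(x[perm, ], y[perm], grid)$report$cv_score
  expect_equal(s1, s2)
})

test_that("shuffled labels never look optimistic under LOO", {
  # leave-one-out is pessimistically biased under label permutation (the
  # held-out sample's class is under-represented in its training fold), so
  # the null distribution sits at or below chance; the guard that matters
  # is the absence of optimism.
  set.seed(6)
  scores <- replicate(30, {
    x <- matrix(rnorm(12), ncol = 1)
    y <- sample(rep(c("healthy", "MS"), each = 6))
    loo_grid_search(x, y, list(svm_config("linear", C = 1)))$best_score
  })
  se <- sqrt(0.25 / (30 * 12))
  expect_lt(mean(scores), 0.5 + 4 * se + 0.05)
})

test_that("confusion metrics match the defining ratios on all small tables", {
  counts <- expand.grid(TP = 0:12, TN = 0:12, FP = 0:6, FN = 0:6)
  counts <- counts[rowSums(counts) > 0, ]
  m <- confusion_metrics(counts$TP, counts$TN, counts$FP, counts$FN)
  with(counts, {
    ok <- (TP + TN + FP + FN) > 0
    expect_equal(m$ACC[ok], ((TP + TN) / (TP + TN + FP + FN))[ok])
    pos <- (TP + FN) > 0
    expect_equal(m$SEN[pos], (TP / (TP + FN))[pos])
    neg <- (TN + FP) > 0
    expect_equal(m$SPE[neg], (TN / (TN + FP))[neg])
    expect_equal(m$FPR[neg], (FP / (FP + TN))[neg])
    pp <- (TP + FP) > 0
    expect_equal(m$PREC[pp], (TP / (TP + FP))[pp])
    f1ok <- pos & pp & (m$PREC + m$SEN) > 0
    expect_equal(m$F1[f1ok],
                 (2 * m$PREC * m$SEN / (m$PREC + m$SEN))[f1ok])
  })
  # worked example: TP=8, TN=9, FP=0, FN=1
  one <- confusion_metrics(8, 9, 0, 1)
  expect_equal(one$ACC, 17 / 18)
  expect_equal(one$SEN, 8 / 9)
  expect_equal(one$SPE, 1)
})

test_that("ROC curves are monotone, exact for perfect scores, and chance for noise", {
  labs <- rep(c("MS", "healthy"), each = 9)
  perfect <- c(rnorm(9, 5, 0.1), rnorm(9, -5, 0.1))
  rc <- roc_curve(perfect, labs)
  expect_equal(rc$auc, 1)
  expect_equal(rc$roc$FPR[1], 0)
  expect_equal(rc$roc$SEN[nrow(rc$roc)], 1)
  expect_true(all(diff(rc$roc$FPR) >= 0))

  set.seed(8)
  big_labs <- sample(rep(c("MS", "healthy"), each = 500))
  noise <- rnorm(1000)
  expect_lt(abs(roc_curve(noise, big_labs)$auc - 0.5), 0.06)

  # AUC is invariant under monotone score transformations
  sc <- rnorm(40); labs40 <- sample(rep(c("MS", "healthy"), each = 20))
  expect_equal(roc_curve(sc, labs40)$auc,
               roc_curve(exp(2 * sc) + 3, labs40)$auc)

  expect_warning(roc_curve(rnorm(5), rep("MS", 5)), "single-class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(60)
  labs <- sample(rep(c("MS", "healthy"), each = 30))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labs, predictor = sc, levels = c("healthy", "MS"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_curve(sc, labs)$auc, ref, tolerance = 1e-12)
})

test_that("classifier evaluation assembles counts, metrics and ROC", {
  set.seed(10)
  x <- matrix(c(rnorm(10, -2), rnorm(10, 2)), ncol = 1)
  y <- rep(c("healthy", "MS"), each = 10)
  gs <- loo_grid_search(x, y, list(svm_config("linear", C = 1)))
  ev <- evaluate_classifier(gs$model, x, y)
  expect_equal(ev$metrics$ACC, 1)
  expect_equal(ev$auc, 1)
  expect_equal(with(ev$metrics, TP + TN + FP + FN), 20)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_warning(evaluate_classifier(gs$model, x[1:3, , drop = FALSE],
                                     rep("MS", 3)), "single-class")
})
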