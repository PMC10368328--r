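test_that("a perfectly separating feature yields perfect CV metrics", {
  d <- makeToyMatrix(n0 = 20, n1 = 20, p = 1, signalCols = 1)
  cv <- quietCV(d$X, d$y, cvConfig(nIterations = 100, masterSeed = 2))
  expect_equal(cvMeans(cv)[["accuracy"]], 1.0)
  expect_equal(cvMeans(cv)[["auroc"]], 1.0)
  # and in a single full-data fit, training accuracy is 1 and that
  # feature's |coefficient| dominates any noise feature
  d2 <- makeToyMatrix(n0 = 30, n1 = 30, p = 6, signalCols = 3)
  fit <- fitStandardizedLogistic(d2$X, d2$y)
  expect_identical(predict(fit, d2$X, type = "class"),
                   ifelse(d2$y == "pos", "pos", "neg"))
  expect_identical(which.max(abs(fit@coefficients)), c(`toy:3` = 3L))
})

test_that("constant features get exactly zero weight", {
  d <- makeToyMatrix(n0 = 15, n1 = 15, p = 4, signalCols = 2)
  d$X[, 4] <- 7
  fit <- fitStandardizedLogistic(d$X, d$y)
  expect_identical(unname(fit@coefficients[4]), 0)
  coefs <- fullDataCoefficients(d$X, d$y)
  expect_identical(unname(coefs[4]), 0)
})

test_that("duplicated identical features receive equal coefficients", {
  d <- makeToyMatrix(n0 = 25, n1 = 25, p = 5, signalCols = 1, flip = 0.2,
                     seed = 6)
  d$X[, 2] <- d$X[, 1]
  fit <- fitStandardizedLogistic(d$X, d$y)
  expect_equal(fit@coefficients[[1]], fit@coefficients[[2]],
               tolerance = 1e-8)
})

test_that("single-class labels are rejected", {
  d <- makeToyMatrix()
  expect_error(fitStandardizedLogistic(d$X, rep("pos", nrow(d$X))),
               "2 classes")
})

test_that("pure-noise features score at chance level", {
  set.seed(10)
  X <- matrix(rbinom(200 * 20, 1, 0.5), 200, 20)
  y <- rep(c("a", "b"), each = 100)
  cv <- quietCV(X, y, cvConfig(nIterations = 100, masterSeed = 3))
  expect_gt(cvMeans(cv)[["accuracy"]], 0.40)
  expect_lt(cvMeans(cv)[["accuracy"]], 0.62)
  expect_gt(cvMeans(cv)[["auroc"]], 0.38)
  expect_lt(cvMeans(cv)[["auroc"]], 0.62)
})

test_that("a constant feature reduces to majority-vote accuracy", {
  # majority-vote oracle: expected accuracy is the mean test-set fraction
  # of the training-majority class, simulated independently
  n0 <- 58; n1 <- 76; n <- n0 + n1
  y01 <- rep(c(0, 1), c(n0, n1))
  set.seed(77)
  oracle <- mean(replicate(4000, {
    te <- sample.int(n, 40)
    maj <- as.integer(mean(y01[-te]) > 0.5)
    mean(y01[te] == maj)
  }))
  X <- matrix(1, n, 1)
  y <- rep(c("C3", "C4"), c(n0, n1))
  cv <- quietCV(X, y, cvConfig(nIterations = 200, masterSeed = 4))
  expect_equal(cvMeans(cv)[["accuracy"]], oracle, tolerance = 0.02)
  expect_equal(oracle, 76 / 134, tolerance = 0.02)
})

test_that("standardization and fit use the training portion only", {
  d <- makeToyMatrix(n0 = 20, n1 = 20, p = 6, signalCols = 1, flip = 0.15,
                     seed = 9)
  cfg <- cvConfig(nIterations = 20, masterSeed = 5)
  cv1 <- quietCV(d$X, d$y, cfg)
  X2 <- d$X
  X2[7, ] <- X2[7, ] + 1000  # corrupt one sample's features
  cv2 <- quietCV(X2, d$y, cfg)
  for (i in seq_len(20)) {
    te <- cv1@testIndex[i, ]
    if (!7 %in% te) next
    others <- te != 7
    # the corrupted sample sat in the test set: every other test sample's
    # prediction must be untouched (no leakage into standardization/fit)
    expect_identical(cv1@probabilities[i, others],
                     cv2@probabilities[i, others])
  }
})

test_that("CV summaries are pure functions of (X, y, config)", {
  d <- makeToyMatrix(n0 = 16, n1 = 24, p = 8, signalCols = 2, flip = 0.3)
  cfg <- cvConfig(nIterations = 30, masterSeed = 11)
  cv1 <- quietCV(d$X, d$y, cfg)
  cv2 <- quietCV(d$X, d$y, cfg)
  expect_identical(cvIterations(cv1), cvIterations(cv2))
  expect_identical(cv1@probabilities, cv2@probabilities)
  cv3 <- quietCV(d$X, d$y, cvConfig(nIterations = 30, masterSeed = 12))
  expect_false(identical(cvIterations(cv1), cvIterations(cv3)))
})

test_that("metric means lie in the hull of per-iteration values", {
  d <- makeToyMatrix(n0 = 18, n1 = 22, p = 10, signalCols = 1,
                     flip = 0.25, seed = 21)
  cv <- quietCV(d$X, d$y, cvConfig(nIterations = 50, masterSeed = 13))
  it <- cvIterations(cv)
  for (mname in names(cvMeans(cv))) {
    expect_gte(cvMeans(cv)[[mname]], min(it[[mname]]))
    expect_lte(cvMeans(cv)[[mname]], max(it[[mname]]))
    expect_true(all(it[[mname]] >= 0 & it[[mname]] <= 1))
  }
})

test_that("permuted labels keep class counts and erase signal", {
  d <- makeToyMatrix(n0 = 40, n1 = 60, p = 4, signalCols = 1, flip = 0.05,
                     seed = 30)
  cfg <- cvConfig(nIterations = 60, masterSeed = 14)
  null <- suppressWarnings(permutedLabelCV(d$X, d$y, cfg))
  # permutation preserves the label multiset
  expect_identical(as.vector(sort(table(null@trueClass))),
                   as.vector(sort(table(d$y == "pos"))))
  # chance level: within 0.08 of the majority fraction
  expect_lt(abs(cvMeans(null)[["accuracy"]] - 0.6), 0.08)
  # determinism
  null2 <- suppressWarnings(permutedLabelCV(d$X, d$y, cfg))
  expect_identical(cvIterations(null), cvIterations(null2))
  # permutation gap on signal data: true beats permuted at p < 0.001
  true <- quietCV(d$X, d$y, cfg)
  cmp <- compareMetricDistributions(true, null)
  expect_gt(cmp$statistic, 0)
  expect_true(cmp$significant)
})

test_that("metric-distribution comparison follows Student/Bonferroni", {
  x <- c(0.9, 0.91, 0.92, 0.9, 0.89)
  same <- compareMetricDistributions(x, x, alpha = 0.001, m = 1)
  expect_false(same$significant)
  # closed-form t for clearly separated distributions
  set.seed(1)
  a <- rnorm(500, 0.99, 0.01); b <- rnorm(500, 0.85, 0.01)
  big <- compareMetricDistributions(a, b, m = 100)
  sp <- sqrt(((499 * var(a)) + (499 * var(b))) / 998)
  tExpected <- (mean(a) - mean(b)) / (sp * sqrt(2 / 500))
  expect_equal(big$statistic, tExpected, tolerance = 1e-10)
  expect_true(big$significant)
  expect_equal(big$adjustedP, min(1, 100 * big$p))
  # a family-size correction can push a nominally small p past alpha
  set.seed(2)
  c1 <- rnorm(40, 0.90, 0.02); c2 <- rnorm(40, 0.915, 0.02)
  mod <- compareMetricDistributions(c1, c2, alpha = 0.001, m = 50)
  expect_equal(mod$adjustedP, min(1, 50 * mod$p))
  expect_false(mod$significant)
  zz <- compareMetricDistributions(rep(1, 5), rep(1, 5))
  expect_equal(zz$p, 1)
  # Welch flag changes the degrees of freedom, not the orientation
  w <- compareMetricDistributions(a, b, m = 100, welch = TRUE)
  expect_gt(w$statistic, 0)
})

test_that("per-group misclassification pools test appearances", {
  # perfect model: every group rate 0
  d <- makeToyMatrix(n0 = 15, n1 = 15, p = 1, signalCols = 1)
  cv <- quietCV(d$X, d$y, cvConfig(nIterations = 40, masterSeed = 16))
  groups <- rep(c("g1", "g2", "g3"), length.out = 30)
  tab <- misclassificationByGroup(cv, groups)
  expect_equal(tab$rate, c(0, 0, 0))
  expect_identical(sum(tab$appearances), length(cv@testIndex))
  # constant features with unbalanced classes: the minority class is
  # misclassified in every test appearance, the majority never
  Xc <- matrix(1, 30, 1)
  yc <- rep(c("neg", "pos"), c(10, 20))
  cvc <- quietCV(Xc, yc, cvConfig(nIterations = 40, masterSeed = 16))
  tabc <- misclassificationByGroup(cvc, yc)
  expect_equal(tabc$rate[tabc$group == "neg"], 1)
  expect_equal(tabc$rate[tabc$group == "pos"], 0)
  # invariance to group renaming
  ren <- misclassificationByGroup(cvc, ifelse(yc == "neg", "zz", "aa"))
  expect_equal(sort(ren$rate), sort(tabc$rate))
})

test_that("the resample guard rejects impossibly small datasets", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(
    repeatedSubsampleCV(X, c("a", "a", "a", "b"),
                        cvConfig(nIterations = 5, masterSeed = 1)),
    "too small")
})

test_that("the ridge fit agrees with an independent implementation", {
  skip_if_not_installed("glmnet")
  set.seed(70)
  n <- 90; p <- 25
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(X) <- paste0("g:", seq_len(p))
  y <- rep(c("C3", "C4"), c(40, 50))
  X[, 4] <- as.numeric(y == "C4"); X[sample(n, 12), 4] <- 0
  fit <- fitStandardizedLogistic(X, y)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(X^2) - ctr^2); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  # glmnet scales its penalty by 1/n, so lambda = 1/n matches lambda = 1
  g <- glmnet::glmnet(Xs, as.numeric(y == "C4"), family = "binomial",
                      alpha = 0, lambda = 1 / n, standardize = FALSE,
                      thresh = 1e-14)
  ref <- as.numeric(coef(g))
  expect_lt(max(abs(ref[-1] - fit@coefficients)), 1e-4)
  expect_lt(abs(ref[1] - fit@intercept), 1e-3)
})
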