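test_that("strongestKFeatures ranks by |coefficient| with ap tie-breaks", {
  coefs <- setNames(c(0.2, -1.5, 0.0, 0.7),
                    paste0("g:", 1:4))
  top2 <- strongestKFeatures(coefs, k = 2)
  expect_identical(featureIds(top2), c("g:2", "g:4"))  # ap order
  expect_identical(top2@provenance, "v2")
  # k >= feature count returns everything
  expect_identical(featureIds(strongestKFeatures(coefs, k = 10)),
                   names(coefs))
  # magnitude tie goes to the earlier position
  tie <- setNames(c(0.1, 0.5, 0.2, -0.5), paste0("g:", c(3, 5, 8, 10)))
  expect_identical(featureIds(strongestKFeatures(tie, k = 1)), "g:5")
  expect_error(strongestKFeatures(numeric(0)), "empty")
})

test_that("rfe path has the stated shape and bookkeeping", {
  d <- makeToyMatrix(n0 = 20, n1 = 20, p = 7, signalCols = 2, flip = 0.2,
                     seed = 41)
  cfg <- cvConfig(nIterations = 25, masterSeed = 17)
  path <- suppressWarnings(rfeCV(d$X, d$y, cfg, minFeatures = 2))
  st <- path@steps
  # p - minFeatures + 1 steps, one feature dropped per step
  expect_equal(nrow(st), 7 - 2 + 1)
  expect_identical(st$nFeatures, as.integer(7:2))
  expect_true(all(!is.na(st$eliminated[-nrow(st)])))
  expect_true(is.na(st$eliminated[nrow(st)]))
  # strict subset chain
  for (k in 2:nrow(st)) {
    prev <- activeFeaturesAt(path, k - 1)
    cur <- activeFeaturesAt(path, k)
    expect_true(all(cur %in% prev))
    expect_equal(length(cur), length(prev) - 1L)
  }
  # a matrix with exactly minFeatures columns gives a single-step path
  single <- suppressWarnings(
    rfeCV(d$X[, 1:2], d$y, cfg, minFeatures = 2))
  expect_equal(nrow(single@steps), 1L)
  expect_true(is.na(single@steps$eliminated))
  expect_error(rfeCV(d$X, d$y, cfg, minFeatures = 0), "minFeatures")
})

test_that("an informative column survives elimination to the last step", {
  set.seed(50)
  n <- 120
  X <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  y <- rep(c("C3", "C4"), each = 60)
  X[, 3] <- as.numeric(y == "C4")
  colnames(X) <- paste0("g:", 1:5)
  path <- suppressWarnings(
    rfeCV(X, y, cvConfig(nIterations = 50, masterSeed = 18)))
  for (k in seq_len(nrow(path@steps)))
    expect_true("g:3" %in% activeFeaturesAt(path, k))
  expect_true("g:3" %in%
                featureIds(optimalSubset(path, 2)$featureSet))
})

test_that("optimalSubset applies the budget, tie-breaks and zone flag", {
  fakePath <- function(acc, auroc = rep(0.9, length(acc)), nmax) {
    nf <- seq(nmax, by = -1, length.out = length(acc))
    ids <- paste0("g:", seq_len(nmax))
    new("RFEPath",
        steps = data.frame(nFeatures = as.integer(nf), accuracy = acc,
                           auroc = auroc, precision = acc, recall = acc,
                           f1 = acc,
                           eliminated = c(ids[seq_len(length(acc) - 1)],
                                          NA)),
        featureIds = ids,
        columnMeta = data.frame(gene = "g", ap = seq_len(nmax)),
        config = list())
  }
  # accuracies at 10,9,...,2 features; equal maxima at 5 and 3 features
  acc <- c(0.91, 0.90, 0.90, 0.89, 0.88, 0.95, 0.92, 0.95, 0.90)
  opt <- optimalSubset(fakePath(acc, nmax = 10), maxFeatures = 10)
  expect_equal(opt$nFeatures, 3L)
  expect_true(opt$inZone)
  expect_equal(opt$metrics[["accuracy"]], 0.95)
  # uniformly poor path: best-of-bad with in-zone FALSE
  flat <- optimalSubset(fakePath(rep(0.5, 9), nmax = 10))
  expect_false(flat$inZone)
  expect_equal(flat$metrics[["accuracy"]], 0.5)
  # a better step above the budget is ignored
  acc12 <- c(0.99, rep(0.8, 10))  # best at 12 features
  opt12 <- optimalSubset(fakePath(acc12, nmax = 12), maxFeatures = 10)
  expect_lte(opt12$nFeatures, 10L)
  expect_equal(opt12$metrics[["accuracy"]], 0.8)
  # AUROC breaks remaining ties
  accA <- c(0.9, 0.9, 0.9)
  aurA <- c(0.7, 0.95, 0.8)
  optA <- optimalSubset(fakePath(accA, aurA, nmax = 4), maxFeatures = 4)
  expect_equal(optA$nFeatures, 2L)  # fewest features wins first
})

test_that("rfe recovers planted columns among many noise columns", {
  # high-penetrance planted signal among 100+ noise columns; the optimal
  # subset should recover nearly all planted columns in >= 9/10 seeds
  successes <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 100; p <- 104
    X <- matrix(rbinom(n * p, 1, runif(p, 0.1, 0.5)), n, p, byrow = FALSE)
    y <- rep(c("C3", "C4"), each = 50)
    planted <- c(11, 40, 77, 98)
    for (j in planted) {
      X[, j] <- as.numeric(y == "C4")
      k <- sample(n, 8)  # 8% flips: high but imperfect penetrance
      X[k, j] <- 1 - X[k, j]
    }
    colnames(X) <- paste0("g:", seq_len(p))
    path <- suppressWarnings(
      rfeCV(X, y, cvConfig(nIterations = 30, masterSeed = 500 + s)))
    got <- featureIds(optimalSubset(path, maxFeatures = 10)$featureSet)
    if (sum(paste0("g:", planted) %in% got) >= length(planted) - 1)
      successes <- successes + 1L
  }
  expect_gte(successes, 9L)
})

test_that("the weakest-rank elimination criterion is available", {
  d <- makeToyMatrix(n0 = 20, n1 = 20, p = 6, signalCols = 1, flip = 0.1,
                     seed = 60)
  cfg <- cvConfig(nIterations = 20, masterSeed = 19)
  p1 <- suppressWarnings(rfeCV(d$X, d$y, cfg))
  p2 <- suppressWarnings(rfeCV(d$X, d$y, cfg, criterion = "weakest-rank"))
  # both keep the signal column to the end
  expect_true("toy:1" %in% activeFeaturesAt(p1, nrow(p1@steps)))
  expect_true("toy:1" %in% activeFeaturesAt(p2, nrow(p2@steps)))
})

test_that("rfe path serializes to JSON", {
  d <- makeToyMatrix(n0 = 12, n1 = 12, p = 4, signalCols = 1)
  path <- suppressWarnings(
    rfeCV(d$X, d$y, cvConfig(nIterations = 10, masterSeed = 20)))
  js <- jsonlite::fromJSON(rfePathToJSON(path))
  expect_identical(js$featureIds, featureIds(path))
  expect_equal(nrow(js$steps), nrow(path@steps))
})
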