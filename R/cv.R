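#' A fitted standardized ridge-logistic classifier
#'
#' Stores the decision-function weights on the standardized feature scale
#' together with the centering/scaling parameters learned from the
#' training data, so held-out samples are transformed with training
#' statistics only.
#'
#' @slot coefficients per-feature weights (standardized scale)
#' @slot intercept scalar intercept
#' @slot center,scale per-feature training mean and (population) standard
#'   deviation; constant features get scale 1 and weight exactly 0
#' @slot classes the two class labels, negative first
#' @slot positiveClass label treated as class 1
#' @export
setClass("FittedModel",
  slots = c(coefficients = "numeric", intercept = "numeric",
            center = "numeric", scale = "numeric", classes = "character",
            positiveClass = "character"))

setMethod("show", "FittedModel", function(object) {
  cat("FittedModel: ", length(object@coefficients),
      " features, positive class '", object@positiveClass, "'\n", sep = "")
})

#' Cross-validation configuration
#'
#' Defaults follow the screen's canonical settings: 500 independent random
#' 70:30 train/test splits, ridge (L2) penalty of unit strength on
#' standardized features.
#'
#' @param nIterations number of random subsampling iterations
#' @param testFraction held-out fraction per split
#' @param lambda ridge penalty (inverse regularization strength 1 /
#'   \code{lambda}); applied to standardized features, intercept
#'   effectively unpenalized
#' @param maxIter,tol IRLS iteration cap and convergence threshold
#' @param masterSeed integer; every source of randomness derives from it
#'   (iteration \code{i} uses seed \code{masterSeed + i}), so any
#'   iteration is reproducible in isolation
#' @param stratified draw test samples per class instead of simple random
#' @param positiveClass optional label to treat as class 1; default is the
#'   lexicographically later label (deterministic AUROC orientation)
#' @return a list of class \code{"cvConfig"}
#' @export
cvConfig <- function(nIterations = 500L, testFraction = 0.30, lambda = 1.0,
                     maxIter = 50L, tol = 1e-9, masterSeed = 1L,
                     stratified = FALSE, positiveClass = NULL) {
  stopifnot(nIterations >= 1L, testFraction > 0, testFraction < 1,
            lambda > 0)
  structure(list(nIterations = as.integer(nIterations),
                 testFraction = testFraction, lambda = lambda,
                 maxIter = as.integer(maxIter), tol = tol,
                 masterSeed = as.integer(masterSeed),
                 stratified = isTRUE(stratified),
                 positiveClass = positiveClass),
            class = "cvConfig")
}

# resolve (X, y) from a FeatureMatrix or plain matrix + labels
.resolveXY <- function(X, y) {
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- phenoLabels(X)
    meta <- columnMeta(X)
    X <- as.matrix(X)
  } else {
    meta <- data.frame(gene = NA_character_, ap = seq_len(ncol(X)))
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
    if (is.null(rownames(X)))
      rownames(X) <- paste0("sample", seq_len(nrow(X)))
  }
  if (!length(y)) stop("no labels available")
  if (length(y) != nrow(X)) stop("labels must cover every sample")
  list(X = X, y = as.character(y), meta = meta)
}

# binary class resolution: negative first, positive later (or as configured)
.resolveClasses <- function(y, config) {
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("need exactly 2 classes, found: ", paste(lev, collapse = ", "))
  pos <- config$positiveClass
  if (is.null(pos)) pos <- lev[2L]
  if (!pos %in% lev) stop("positiveClass '", pos, "' not among labels")
  neg <- setdiff(lev, pos)
  list(classes = c(neg, pos), y01 = as.numeric(y == pos))
}

# seeded random 70:30-style splits with a resample guard: a split whose
# training or test portion lacks a class is redrawn (with a warning)
.makeSplits <- function(y01, config) {
  n <- length(y01)
  nTest <- max(1L, round(config$testFraction * n))
  if (n - nTest < 2L) stop("dataset too small for the requested split")
  counts <- table(y01)
  if (length(counts) < 2L || min(counts) < 2L || nTest < 2L)
    stop("dataset too small: each class needs >= 2 members in every split")
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  train <- test <- vector("list", config$nIterations)
  redraws <- 0L
  for (i in seq_len(config$nIterations)) {
    set.seed(config$masterSeed + i)
    for (attempt in seq_len(1000L)) {
      te <- if (config$stratified) {
        i1 <- which(y01 == 1); i0 <- which(y01 == 0)
        k1 <- round(nTest * length(i1) / n)
        sort(c(sample(i1, k1), sample(i0, nTest - k1)))
      } else sort(sample.int(n, nTest))
      tr <- setdiff(seq_len(n), te)
      if (length(unique(y01[tr])) == 2L && length(unique(y01[te])) == 2L)
        break
      redraws <- redraws + 1L
      te <- NULL
    }
    if (is.null(te))
      stop("could not draw a split with both classes in train and test")
    train[[i]] <- tr
    test[[i]] <- te
  }
  if (redraws > 0L)
    warning(redraws, " split(s) redrawn to keep both classes present")
  list(train = train, test = test, nTest = nTest)
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  n <- nrow(X)
  scl <- sqrt(colMeans(X^2) - ctr^2)  # population sd
  scl[scl == 0] <- 1
  list(Xs = scale(X, center = ctr, scale = scl), center = ctr, scale = scl)
}

#' Fit a ridge-logistic classifier on standardized features
#'
#' Features are centered and scaled with statistics of the supplied data;
#' constant features get weight exactly 0.  The fit is deterministic given
#' its inputs.
#'
#' @param X a [FeatureMatrix-class] or numeric matrix (samples x features)
#' @param y binary labels (taken from \code{X} when it carries them)
#' @param config a [cvConfig()]
#' @return a [FittedModel-class]
#' @export
fitStandardizedLogistic <- function(X, y = NULL, config = cvConfig()) {
  d <- .resolveXY(X, y)
  cl <- .resolveClasses(d$y, config)
  st <- .standardize(d$X)
  fit <- .cppFitRidge(st$Xs, cl$y01, config$lambda, config$maxIter,
                      config$tol)
  new("FittedModel",
      coefficients = setNames(as.numeric(fit$coefficients), colnames(d$X)),
      intercept = as.numeric(fit$intercept),
      center = setNames(st$center, colnames(d$X)),
      scale = setNames(st$scale, colnames(d$X)),
      classes = cl$classes, positiveClass = cl$classes[2L])
}

#' Predict from a FittedModel
#' @param object a [FittedModel-class]
#' @param newdata matrix or [FeatureMatrix-class] with the model's features
#' @param type \code{"prob"} (positive-class probability) or
#'   \code{"class"}
#' @param ... ignored
#' @export
setMethod("predict", "FittedModel",
          function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is(newdata, "FeatureMatrix")) newdata <- as.matrix(newdata)
  Xs <- scale(newdata, center = object@center, scale = object@scale)
  eta <- drop(Xs %*% object@coefficients) + object@intercept
  if (type == "prob") return(1 / (1 + exp(-eta)))
  object@classes[(eta > 0) + 1L]
})

.cvSummaryFromEngine <- function(res, splits, cl, ids, config) {
  it <- as.data.frame(res$metrics)
  names(it) <- c("accuracy", "auroc", "precision", "recall", "f1")
  means <- colMeans(it, na.rm = TRUE)
  new("CVSummary", iterations = it, means = means,
      testIndex = do.call(rbind, splits$test),
      predicted = res$preds, probabilities = res$probs,
      sampleIds = ids, trueClass = as.integer(cl$y01),
      classes = cl$classes, positiveClass = cl$classes[2L],
      config = unclass(config))
}

#' Repeated random-subsampling cross-validation
#'
#' Draws \code{nIterations} independent seeded random train/test splits
#' (70:30 by default).  In each iteration the standardization and the
#' ridge-logistic fit use the training portion only, and accuracy, AUROC,
#' precision, recall and F1 are computed on the untouched test portion.
#' Per-iteration test memberships and predictions are retained for
#' per-group analyses.  The whole summary is a pure function of
#' \code{(X, y, config)}.
#'
#' @param X a [FeatureMatrix-class] or numeric matrix
#' @param y binary labels (taken from \code{X} when it carries them)
#' @param config a [cvConfig()]
#' @return a [CVSummary-class]
#' @export
repeatedSubsampleCV <- function(X, y = NULL, config = cvConfig()) {
  d <- .resolveXY(X, y)
  cl <- .resolveClasses(d$y, config)
  splits <- .makeSplits(cl$y01, config)
  res <- .cppCV(d$X, cl$y01, splits$train, splits$test, config$lambda,
                config$maxIter, config$tol)
  .cvSummaryFromEngine(res, splits, cl, rownames(d$X), config)
}

#' Decision-function coefficients from a single full-data fit
#'
#' Fits once on all samples (standardization on the full dataset) and
#' returns the signed coefficients aligned to the feature metadata; this
#' is the coefficient vector that feeds the strongest-feature (v2)
#' selection.
#'
#' @inheritParams repeatedSubsampleCV
#' @return named numeric vector of coefficients, with the intercept as
#'   attribute \code{"intercept"}
#' @export
fullDataCoefficients <- function(X, y = NULL, config = cvConfig()) {
  fit <- fitStandardizedLogistic(X, y, config)
  structure(fit@coefficients, intercept = fit@intercept)
}

#' Cross-validation under a label permutation null
#'
#' Replaces the labels by one seeded random permutation (class counts
#' preserved) and runs the identical repeated-subsampling procedure, so
#' the resulting metric distribution is the chance-level reference for
#' [compareMetricDistributions()].
#'
#' @inheritParams repeatedSubsampleCV
#' @return a [CVSummary-class]
#' @export
permutedLabelCV <- function(X, y = NULL, config = cvConfig()) {
  d <- .resolveXY(X, y)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$masterSeed)
  yperm <- sample(d$y)
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  repeatedSubsampleCV(d$X, yperm, config)
}

#' Compare two per-iteration metric distributions
#'
#' Two-sided two-sample Student's t-test (classical equal-variance by
#' default; Welch behind a flag) with Bonferroni adjustment for a family
#' of \code{m} comparisons.  When both samples have zero variance and
#' equal means the p-value is 1 by convention.
#'
#' @param a,b numeric vectors of per-iteration metric values, or
#'   [CVSummary-class] objects (then \code{metric} selects the column)
#' @param alpha significance level applied to the adjusted p
#' @param m family size for the Bonferroni adjustment
#' @param welch use the Welch unequal-variance test
#' @param metric metric column when \code{a}/\code{b} are CVSummary
#' @return data.frame with \code{statistic}, \code{p}, \code{adjustedP}
#'   (\code{= min(1, m * p)}) and \code{significant}
#' @export
compareMetricDistributions <- function(a, b, alpha = 0.001, m = 1L,
                                       welch = FALSE,
                                       metric = "accuracy") {
  if (is(a, "CVSummary")) a <- cvIterations(a)[[metric]]
  if (is(b, "CVSummary")) b <- cvIterations(b)[[metric]]
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (sd(a) == 0 && sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  adj <- min(1, m * tt$p.value)
  data.frame(statistic = tt$statistic, p = tt$p.value, adjustedP = adj,
             significant = adj < alpha)
}

#' Misclassification rate per sample group
#'
#' Pools all test-set appearances over the iterations of a CV run: for
#' each group, rate = misclassified appearances / total appearances.
#' Groups that never appear in a test set get an \code{NA} rate
#' (undefined, not 0).
#'
#' @param cv a [CVSummary-class] with retained predictions
#' @param groups per-sample categories: a vector parallel to
#'   \code{sampleIds(cv)} or named by sample id
#' @return data.frame with \code{group}, \code{appearances},
#'   \code{misclassified}, \code{rate}
#' @export
misclassificationByGroup <- function(cv, groups) {
  stopifnot(is(cv, "CVSummary"))
  ids <- cv@sampleIds
  if (!is.null(names(groups))) groups <- groups[ids]
  if (length(groups) != length(ids))
    stop("'groups' must cover every sample")
  groups <- as.character(groups)
  idx <- as.vector(t(cv@testIndex))
  miss <- as.vector(t(cv@predicted)) != cv@trueClass[idx]
  g <- groups[idx]
  lev <- sort(unique(groups))
  app <- as.integer(table(factor(g, levels = lev)))
  bad <- vapply(lev, function(l) sum(miss[g == l]), integer(1))
  data.frame(group = lev, appearances = app, misclassified = bad,
             rate = ifelse(app > 0, bad / app, NA_real_))
}
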