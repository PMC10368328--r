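#' Select the k features with the largest absolute coefficients
#'
#' The v2 selection rule: rank features by the absolute value of the
#' full-data decision-function coefficients and keep the top \code{k}
#' (all features when \code{k} exceeds the feature count).  Ties are
#' broken in favour of the earlier alignment position.
#'
#' @param coefs named coefficient vector as returned by
#'   [fullDataCoefficients()]
#' @param k number of features to keep
#' @param meta optional per-feature metadata data.frame (gene, ap) aligned
#'   with \code{coefs}; parsed from the \code{"gene:ap"} names when absent
#' @return a [FeatureSet-class] with provenance \code{"v2"}, features in
#'   alignment order
#' @export
strongestKFeatures <- function(coefs, k = 10L, meta = NULL) {
  if (length(coefs) == 0L) stop("empty coefficient vector")
  stopifnot(k >= 1L)
  if (is.null(meta)) meta <- .parseFeatureIds(names(coefs))
  ord <- order(-abs(coefs), seq_along(coefs))
  keep <- sort(ord[seq_len(min(k, length(coefs)))])
  new("FeatureSet",
      features = data.frame(gene = meta$gene[keep], ap = meta$ap[keep],
                            id = names(coefs)[keep]),
      provenance = "v2")
}

.parseFeatureIds <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, "", 1L),
             ap = as.integer(vapply(parts, function(p) p[length(p)], "")))
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from all supplied features, runs the full repeated-subsampling
#' CV at every step, records the five metric means, computes each active
#' feature's mean absolute standardized coefficient across the step's
#' fits, eliminates the minimum (the "most consistent weakest" feature;
#' ties eliminate the later column), and repeats down to
#' \code{minFeatures}.  The recursion never stops early on accuracy
#' plateaus, so performance is always known for feature sets of every
#' size.  The same seeded splits are reused at every step.
#'
#' @param X a [FeatureMatrix-class] or numeric matrix
#' @param y binary labels (taken from \code{X} when it carries them)
#' @param config a [cvConfig()]
#' @param minFeatures smallest active set evaluated (>= 1; default 2)
#' @param criterion \code{"mean-abs-coef"} (minimum mean |coefficient|
#'   across fits) or \code{"weakest-rank"} (feature most often ranked
#'   weakest within single fits)
#' @return an [RFEPath-class]
#' @export
rfeCV <- function(X, y = NULL, config = cvConfig(), minFeatures = 2L,
                  criterion = c("mean-abs-coef", "weakest-rank")) {
  criterion <- match.arg(criterion)
  if (minFeatures < 1L) stop("minFeatures must be >= 1")
  d <- .resolveXY(X, y)
  if (ncol(d$X) < minFeatures)
    stop("need at least ", minFeatures, " feature columns")
  cl <- .resolveClasses(d$y, config)
  splits <- .makeSplits(cl$y01, config)
  res <- .cppRFE(d$X, cl$y01, splits$train, splits$test, config$lambda,
                 config$maxIter, config$tol, as.integer(minFeatures),
                 if (criterion == "mean-abs-coef") 0L else 1L)
  ids <- colnames(d$X)
  steps <- data.frame(nFeatures = as.integer(res$nFeatures),
                      as.data.frame(res$stepMetrics))
  names(steps)[2:6] <- c("accuracy", "auroc", "precision", "recall", "f1")
  steps$eliminated <- ifelse(is.na(res$eliminated), NA_character_,
                             ids[res$eliminated])
  new("RFEPath", steps = steps, featureIds = ids,
      columnMeta = d$meta, config = unclass(config))
}

#' Active feature set at a given RFE step
#' @param path an [RFEPath-class]
#' @param step 1-based step index
#' @return character vector of feature ids active at that step, in
#'   original column order
#' @export
activeFeaturesAt <- function(path, step) {
  stopifnot(is(path, "RFEPath"), step >= 1L, step <= nrow(path@steps))
  gone <- path@steps$eliminated[seq_len(step - 1L)]
  setdiff(path@featureIds, gone)
}

#' Extract the optimal small feature set from an RFE path
#'
#' Among the steps with at most \code{maxFeatures} active features,
#' returns the one with the highest mean CV accuracy; ties go to the
#' smaller feature set, then to the higher mean AUROC.  The in-zone flag
#' reports whether that optimum reaches the accuracy floor (the
#' "optimal zone": <= 10 features and accuracy >= 0.9).
#'
#' @param path an [RFEPath-class]
#' @param maxFeatures feature budget (default 10)
#' @param accuracyFloor accuracy defining the optimal zone (default 0.9)
#' @return list with \code{featureSet} (a [FeatureSet-class], provenance
#'   \code{"v3"}), \code{metrics} (named metric means of the chosen step),
#'   \code{nFeatures}, \code{step} (index into the path) and
#'   \code{inZone}
#' @export
optimalSubset <- function(path, maxFeatures = 10L, accuracyFloor = 0.9) {
  stopifnot(is(path, "RFEPath"))
  st <- path@steps
  cand <- which(st$nFeatures <= maxFeatures)
  if (!length(cand))
    stop("no RFE step with <= ", maxFeatures, " features")
  ord <- cand[order(-st$accuracy[cand], st$nFeatures[cand],
                    -st$auroc[cand])]
  best <- ord[1L]
  ids <- activeFeaturesAt(path, best)
  meta <- path@columnMeta[match(ids, path@featureIds), , drop = FALSE]
  fs <- new("FeatureSet",
            features = data.frame(gene = meta$gene, ap = meta$ap,
                                  id = ids),
            provenance = "v3")
  metrics <- unlist(st[best, c("accuracy", "auroc", "precision",
                               "recall", "f1")])
  list(featureSet = fs, metrics = metrics,
       nFeatures = st$nFeatures[best], step = best,
       inZone = st$accuracy[best] >= accuracyFloor)
}

#' Serialize an RFE path to JSON
#' @param path an [RFEPath-class]
#' @param file optional output file
#' @return JSON string (invisibly when written)
#' @export
rfePathToJSON <- function(path, file = NULL) {
  js <- jsonlite::toJSON(list(featureIds = path@featureIds,
                              steps = path@steps),
                         auto_unbox = TRUE, na = "null", digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
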