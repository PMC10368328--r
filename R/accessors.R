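#' Accessors for siteScreen objects
#'
#' Small generics giving read access to the slots of the core classes
#' without touching \code{@}.
#'
#' @param x a siteScreen object
#' @return \code{geneName}: the gene name; \code{sampleIds}: character
#'   vector of sample identifiers; \code{phenoLabels}: per-sample phenotype
#'   labels (length 0 when unlabeled); \code{sampleGroups}: data.frame of
#'   per-sample annotations; \code{referenceId}: the reference sample id or
#'   \code{NA}; \code{featureIds}: \code{"gene:ap"} feature identifiers;
#'   \code{columnMeta}: per-feature metadata; \code{cvMeans}: named metric
#'   means; \code{cvIterations}: per-iteration metric data.frame.
#' @name accessors
#' @aliases geneName sampleIds phenoLabels sampleGroups referenceId
#'   featureIds columnMeta cvMeans cvIterations
NULL

#' @rdname accessors
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("phenoLabels", function(x) standardGeneric("phenoLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("columnMeta", function(x) standardGeneric("columnMeta"))
#' @rdname accessors
#' @export
setGeneric("cvMeans", function(x) standardGeneric("cvMeans"))
#' @rdname accessors
#' @export
setGeneric("cvIterations", function(x) standardGeneric("cvIterations"))

#' @rdname accessors
setMethod("geneName", "LabeledAlignment", function(x) x@gene)
#' @rdname accessors
setMethod("sampleIds", "LabeledAlignment", function(x) names(x@seqs))
#' @rdname accessors
setMethod("phenoLabels", "LabeledAlignment", function(x) {
  if (length(x@labels)) setNames(x@labels, names(x@seqs)) else character(0)
})
#' @rdname accessors
setMethod("sampleGroups", "LabeledAlignment", function(x) x@groups)
#' @rdname accessors
setMethod("referenceId", "LabeledAlignment", function(x) {
  if (length(x@referenceId)) x@referenceId else NA_character_
})
#' @rdname accessors
setMethod("geneName", "ColumnKeys", function(x) x@gene)
#' @rdname accessors
setMethod("sampleIds", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("phenoLabels", "FeatureMatrix", function(x) {
  if (length(x@labels)) setNames(x@labels, rownames(x@values))
  else character(0)
})
#' @rdname accessors
setMethod("featureIds", "FeatureMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("columnMeta", "FeatureMatrix", function(x) x@columnMeta)
#' @rdname accessors
setMethod("featureIds", "FeatureSet", function(x) x@features$id)
#' @rdname accessors
setMethod("featureIds", "RFEPath", function(x) x@featureIds)
#' @rdname accessors
setMethod("columnMeta", "RFEPath", function(x) x@columnMeta)
#' @rdname accessors
setMethod("cvMeans", "CVSummary", function(x) x@means)
#' @rdname accessors
setMethod("cvIterations", "CVSummary", function(x) x@iterations)

#' Number of sequences / samples
#' @param x a LabeledAlignment or FeatureMatrix
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname nSamples
setMethod("nSamples", "LabeledAlignment", function(x) length(x@seqs))
#' @rdname nSamples
setMethod("nSamples", "FeatureMatrix", function(x) nrow(x@values))

#' Alignment as a character matrix (samples x columns)
#' @param x a LabeledAlignment
#' @param ... ignored
#' @export
setMethod("as.matrix", "LabeledAlignment", function(x, ...) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
  rownames(m) <- names(x@seqs)
  m
})

#' Encoded feature values as an integer matrix
#' @param x a FeatureMatrix
#' @param ... ignored
#' @export
setMethod("as.matrix", "FeatureMatrix", function(x, ...) x@values)

setMethod("show", "LabeledAlignment", function(object) {
  lab <- phenoLabels(object)
  cat("LabeledAlignment '", object@gene, "': ", nSamples(object),
      " sequences x ", Biostrings::width(object@seqs)[1L], " columns\n",
      sep = "")
  if (length(lab)) {
    tb <- table(lab, useNA = "ifany")
    cat("  labels: ", paste(names(tb), tb, sep = "=", collapse = ", "),
        "\n", sep = "")
  } else cat("  unlabeled\n")
  if (length(object@referenceId))
    cat("  reference:", object@referenceId, "\n")
})

setMethod("show", "ColumnKeys", function(object) {
  n <- lengths(object@keys)
  cat("ColumnKeys '", object@gene, "': ", length(object@keys),
      " columns (", sum(n == 1L), " invariant, ", sum(n == 2L),
      " binary, ", sum(n > 2L), " multistate)\n", sep = "")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix: ", nrow(object@values), " samples x ",
      ncol(object@values), " features (",
      length(unique(object@columnMeta$gene)), " gene(s))\n", sep = "")
  if (length(object@labels)) {
    tb <- table(object@labels)
    cat("  labels: ", paste(names(tb), tb, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
})

setMethod("show", "CVSummary", function(object) {
  cat("CVSummary: ", nrow(object@iterations), " iterations, positive class '",
      object@positiveClass, "'\n  means: ", sep = "")
  cat(paste(names(object@means), sprintf("%.4f", object@means),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RFEPath", function(object) {
  st <- object@steps
  cat("RFEPath: ", length(object@featureIds), " -> ",
      st$nFeatures[nrow(st)], " features over ", nrow(st),
      " steps; best accuracy ", sprintf("%.4f", max(st$accuracy)),
      "\n", sep = "")
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet (", object@provenance, "): ",
      paste(object@features$id, collapse = ", "), "\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
  np <- vapply(object@genes, nrow, 0L)
  cat("SyntheticTruth: ", length(object@genes), " genes, ",
      sum(np), " planted signal columns\n", sep = "")
})

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport: ", nrow(object@table), " genes\n", sep = "")
  tb <- object@table
  tb <- tb[order(-tb$v1_accuracy), , drop = FALSE]
  print(utils::head(tb[, intersect(
    c("gene", "v1_accuracy", "v2_accuracy", "v3_accuracy", "v3_n_features",
      "in_zone"), names(tb))], 10L), row.names = FALSE)
})
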