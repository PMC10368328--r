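#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom stats cor chisq.test p.adjust pt rbinom runif sd setNames t.test
#' @importFrom utils combn read.delim write.table head
#' @useDynLib siteScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Gapped amino-acid alignment with sample phenotype labels
#'
#' The central input container of the screen: one protein-coding gene's
#' multiple sequence alignment (equal-width, gapped rows over the amino-acid
#' alphabet) together with the binary phenotype label of every sample
#' (for example \code{"C3"} / \code{"C4"}), optional per-sample group
#' annotations (biochemical subtype, Kranz type, lineage) and an optional
#' reference sample used to renumber alignment columns into ungapped
#' residue coordinates.
#'
#' @slot gene single gene name
#' @slot seqs an [Biostrings::AAStringSet] of equal widths; names are the
#'   unique sample identifiers
#' @slot labels character vector parallel to \code{seqs} (length 0 while
#'   unlabeled); at most two distinct values across the object
#' @slot groups data.frame of optional categorical annotations, one row per
#'   sample (zero columns when absent)
#' @slot referenceId sample id used for coordinate renumbering
#'   (length 0 when unset)
#' @seealso [readAlignment()], [attachLabels()], [buildReferenceMap()]
#' @export
setClass("LabeledAlignment",
  slots = c(gene = "character", seqs = "AAStringSet", labels = "character",
            groups = "data.frame", referenceId = "character"))

setValidity("LabeledAlignment", function(object) {
  n <- length(object@seqs)
  msg <- character()
  if (length(object@gene) != 1L || !nzchar(object@gene))
    msg <- c(msg, "'gene' must be a single non-empty string")
  if (n < 1L) msg <- c(msg, "alignment has no sequences")
  w <- Biostrings::width(object@seqs)
  if (n > 0L && (length(unique(w)) != 1L || w[1L] < 1L))
    msg <- c(msg, "all rows must have the same non-zero width")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "sample ids must be unique and non-empty")
  if (length(object@labels) && length(object@labels) != n)
    msg <- c(msg, "'labels' must cover every sample")
  lv <- unique(object@labels[!is.na(object@labels)])
  if (length(lv) > 2L)
    msg <- c(msg, "labels must take at most 2 values")
  if (nrow(object@groups) && nrow(object@groups) != n)
    msg <- c(msg, "'groups' must have one row per sample")
  if (length(object@referenceId) > 1L)
    msg <- c(msg, "'referenceId' must be a single id")
  if (length(object@referenceId) == 1L && !object@referenceId %in% ids)
    msg <- c(msg, "'referenceId' is not a sample id")
  if (length(msg)) msg else TRUE
})

#' Per-column ordinal encoding keys
#'
#' For every alignment column, a bijection from the characters observed in
#' that column (amino-acid letters, ambiguity letters, and the gap
#' character \code{"-"}) to the integer codes \code{0..N-1}, where N is the
#' number of distinct characters in the column.  Codes are assigned in
#' order of descending character frequency, ties broken alphabetically, so
#' code 0 is always the modal state.
#'
#' @slot gene gene name the keys were built from
#' @slot ap integer vector of 1-based alignment positions
#' @slot keys list of named integer vectors, one per column; names are the
#'   characters, values the codes
#' @seealso [buildColumnKeys()], [permuteKeys()]
#' @export
setClass("ColumnKeys",
  slots = c(gene = "character", ap = "integer", keys = "list"))

setValidity("ColumnKeys", function(object) {
  if (length(object@ap) != length(object@keys))
    return("'ap' and 'keys' lengths differ")
  for (k in object@keys) {
    if (!setequal(k, seq_along(k) - 1L))
      return("each column's codes must be exactly 0..N-1")
    if (is.null(names(k)) || anyDuplicated(names(k)))
      return("each column's characters must be uniquely named")
  }
  TRUE
})

#' Ordinally encoded alignment columns as a samples x features matrix
#'
#' @slot values integer matrix, samples in rows (rownames = sample ids),
#'   alignment columns in columns (colnames = \code{"gene:ap"} feature ids)
#' @slot columnMeta data.frame with columns \code{gene} and \code{ap}
#'   (1-based alignment position), one row per feature
#' @slot labels character vector of per-sample phenotype labels
#'   (length 0 when unlabeled)
#' @seealso [encodeAlignment()]
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", columnMeta = "data.frame",
            labels = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != nrow(object@columnMeta))
    msg <- c(msg, "columnMeta must have one row per matrix column")
  if (!all(c("gene", "ap") %in% names(object@columnMeta)))
    msg <- c(msg, "columnMeta needs 'gene' and 'ap' columns")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "matrix must carry sample ids as rownames")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@values))
    msg <- c(msg, "'labels' must cover every sample")
  if (length(msg)) msg else TRUE
})

#' Repeated random-subsampling cross-validation summary
#'
#' Holds the per-iteration test-set metrics (accuracy, AUROC, precision,
#' recall, F1) of a ridge-logistic classifier across seeded random
#' train/test splits, their means, and the per-iteration test memberships
#' and predictions needed for per-group misclassification summaries.
#'
#' @slot iterations data.frame, one row per iteration, columns
#'   \code{accuracy, auroc, precision, recall, f1}
#' @slot means named numeric vector of the five metric means
#' @slot testIndex integer matrix (iterations x test size) of row indices
#'   into the sample vector held out in each iteration
#' @slot predicted integer matrix of predicted classes (1 = positive)
#' @slot probabilities numeric matrix of predicted positive-class
#'   probabilities
#' @slot sampleIds sample identifiers indexing \code{testIndex}
#' @slot trueClass integer vector (0/1) of each sample's true class
#' @slot classes the two class labels, negative first
#' @slot positiveClass the label treated as class 1
#' @slot config the [cvConfig()] list used
#' @export
setClass("CVSummary",
  slots = c(iterations = "data.frame", means = "numeric",
            testIndex = "matrix", predicted = "matrix",
            probabilities = "matrix", sampleIds = "character",
            trueClass = "integer", classes = "character",
            positiveClass = "character", config = "list"))

#' Recursive feature elimination path
#'
#' One row per elimination step: the number of active features, the five
#' cross-validated metric means of a classifier trained on them, and the
#' feature eliminated before the next step (the feature with the lowest
#' mean absolute standardized coefficient across the step's fits).  The
#' path always continues to \code{minFeatures} regardless of accuracy
#' plateaus, so optimal small feature sets can be read off afterwards.
#'
#' @slot steps data.frame with columns \code{nFeatures, accuracy, auroc,
#'   precision, recall, f1, eliminated} (feature id, NA on the final step)
#' @slot featureIds initial feature ids in matrix column order
#' @slot columnMeta per-feature (gene, ap) metadata of the initial set
#' @slot config the [cvConfig()] list used
#' @seealso [rfeCV()], [optimalSubset()]
#' @export
setClass("RFEPath",
  slots = c(steps = "data.frame", featureIds = "character",
            columnMeta = "data.frame", config = "list"))

setValidity("RFEPath", function(object) {
  st <- object@steps
  if (nrow(st) > 1L && any(diff(st$nFeatures) != -1L))
    return("each step must drop exactly one feature")
  TRUE
})

#' An ordered set of selected alignment-column features
#'
#' @slot features data.frame with columns \code{gene}, \code{ap} and
#'   \code{id} (the \code{"gene:ap"} feature identifier)
#' @slot provenance how the set was selected: \code{"v2"} (ten strongest
#'   full-data coefficients), \code{"v3"} (RFE-CV optimum) or
#'   \code{"complex"}
#' @export
setClass("FeatureSet",
  slots = c(features = "data.frame", provenance = "character"))

#' Ground truth of a synthetic screen dataset
#'
#' @slot genes named list; per gene a data.frame of planted signal columns
#'   (ap, class0/class1 residues, lineages carrying the signal, penetrance,
#'   leakage, realized class-conditional alternative-residue frequencies)
#' @slot lineages data.frame with \code{sampleId}, \code{label},
#'   \code{lineage} for every sample
#' @slot spec the generating specification
#' @export
setClass("SyntheticTruth",
  slots = c(genes = "list", lineages = "data.frame", spec = "list"))

#' Full-screen report
#'
#' Per-gene v1 (full-length), v2 (ten strongest features) and v3 (RFE-CV
#' optimal) model summaries plus the retained objects needed for null
#' comparisons and reporting.
#'
#' @slot table per-gene summary data.frame
#' @slot paths named list of [RFEPath-class] objects (v3 stage)
#' @slot cvs named list; per gene a list with CVSummary objects
#'   \code{v1}, \code{v2}, \code{v3}
#' @slot optimal named list of [FeatureSet-class] objects (v3 optima)
#' @slot referenceMaps named list of reference coordinate maps (possibly
#'   empty)
#' @slot config the [cvConfig()] list used
#' @export
setClass("ScreenReport",
  slots = c(table = "data.frame", paths = "list", cvs = "list",
            optimal = "list", referenceMaps = "list", config = "list"))
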