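#' Constituent-subunit roster of the plastid complexes
#'
#' The default multi-protein complex definitions used by the combined
#' screen: NDH (ndhA-ndhK), ATP synthase, cytochrome b6f, Photosystem I,
#' Photosystem II (psbN excluded, as it may not be a constituent member of
#' the supercomplex) and the 50S (rpl32 excluded, being absent from
#' several grass plastomes) and 30S ribosomal subunit gene sets.  The
#' roster is an ordinary named list and fully user-editable.
#'
#' @return named list of character vectors of gene names
#' @export
defaultComplexRoster <- function() {
  list(
    NDH = paste0("ndh", LETTERS[1:11]),
    ATP_synthase = paste0("atp", c("A", "B", "E", "F", "H", "I")),
    cyt_b6f = paste0("pet", c("A", "B", "D", "G", "L", "N")),
    PSI = paste0("psa", c("A", "B", "C", "I", "J")),
    PSII = paste0("psb", c("A", "B", "C", "D", "E", "F", "H", "I", "J",
                           "K", "L", "M", "T", "Z")),
    ribosome_50S = paste0("rpl", c(2, 14, 16, 20, 22, 23, 33, 36)),
    ribosome_30S = paste0("rps", c(2, 3, 4, 7, 8, 11, 12, 14, 15, 16,
                                   18, 19)))
}

#' Read a complex roster from a YAML file
#'
#' The file maps complex names to lists of constituent gene names,
#' mirroring [defaultComplexRoster()]:
#' \preformatted{NDH: [ndhA, ndhB, ndhC]
#' PSI: [psaA, psaB]}
#'
#' @param path YAML file
#' @return named list of character vectors
#' @export
readComplexRoster <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML rosters requires the 'yaml' package")
  roster <- yaml::read_yaml(path)
  lapply(roster, as.character)
}

#' Validate a complex specification
#' @param name complex name
#' @param genes >= 2 distinct constituent gene names
#' @return list with \code{name} and \code{genes}
#' @export
complexSpec <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) < 2L)
    stop("a complex needs >= 2 constituent genes")
  if (anyDuplicated(genes))
    stop("duplicate constituent gene(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  list(name = as.character(name), genes = genes)
}

# subunit display labels: strip the longest common gene-name prefix
# (e.g. ndhA..ndhK -> A..K) when one exists
.subunitLabels <- function(genes) {
  if (length(genes) < 2L) return(setNames(genes, genes))
  chars <- strsplit(genes, "")
  k <- 0L
  repeat {
    nxt <- vapply(chars, function(x)
      if (length(x) > k) x[k + 1L] else NA_character_, "")
    if (anyNA(nxt) || length(unique(nxt)) != 1L) break
    k <- k + 1L
  }
  lab <- if (k >= 2L) substring(genes, k + 1L) else genes
  setNames(lab, genes)
}

#' Concatenate the strongest features of each complex subunit
#'
#' For every constituent gene, fits the full-data ridge-logistic model,
#' keeps its ten (or fewer, for short subunits) strongest features, and
#' concatenates the selected columns in roster order into one combined
#' feature matrix carrying \code{(gene, ap)} metadata.  All subunits must
#' share the same sample set and labels.
#'
#' @param matrices named list of [FeatureMatrix-class], one per gene
#' @param spec a [complexSpec()]
#' @param config a [cvConfig()] (used for the full-data fits)
#' @param k per-subunit feature budget (default 10)
#' @return a combined [FeatureMatrix-class]
#' @export
combineComplex <- function(matrices, spec, config = cvConfig(), k = 10L) {
  miss <- setdiff(spec$genes, names(matrices))
  if (length(miss))
    stop("no feature matrix for gene(s): ", paste(miss, collapse = ", "))
  ids <- sampleIds(matrices[[spec$genes[1L]]])
  lab <- phenoLabels(matrices[[spec$genes[1L]]])
  bad <- Filter(function(g) !identical(sort(sampleIds(matrices[[g]])),
                                       sort(ids)), spec$genes)
  if (length(bad))
    stop("sample-set mismatch across genes: ",
         paste(bad, collapse = ", "))
  pieces <- lapply(spec$genes, function(g) {
    fm <- matrices[[g]]
    # align row order to the first subunit
    j <- match(ids, sampleIds(fm))
    fm@values <- fm@values[j, , drop = FALSE]
    fm@labels <- fm@labels[j]
    if (!identical(unname(phenoLabels(fm)), unname(lab)))
      stop("label mismatch across genes: ", g)
    coefs <- fullDataCoefficients(fm, config = config)
    selectFeatures(fm, strongestKFeatures(coefs, k = k,
                                          meta = columnMeta(fm)))
  })
  new("FeatureMatrix",
      values = do.call(cbind, lapply(pieces, as.matrix)),
      columnMeta = do.call(rbind, lapply(pieces, columnMeta)),
      labels = as.character(lab))
}

#' Screen a plastid complex for an optimal cross-subunit feature set
#'
#' Runs [combineComplex()] then the full RFE-CV on the combined matrix and
#' extracts the optimal set of at most \code{maxFeatures} features.
#' Optimal features are additionally labelled in \code{"Subunit-ap"} form
#' (common gene-name prefix stripped).
#'
#' @inheritParams combineComplex
#' @param maxFeatures budget of the optimal set (default 10)
#' @param minFeatures smallest set evaluated by the RFE (default 2)
#' @param accuracyFloor optimal-zone accuracy threshold
#' @return list with \code{combined} (the combined
#'   [FeatureMatrix-class]), \code{path} (an [RFEPath-class]),
#'   \code{optimal} (as from [optimalSubset()]) and
#'   \code{subunitFeatures} (character vector of \code{"Subunit-ap"}
#'   labels of the optimal set)
#' @export
screenComplex <- function(matrices, spec, config = cvConfig(),
                          maxFeatures = 10L, minFeatures = 2L,
                          accuracyFloor = 0.9, k = 10L) {
  combined <- combineComplex(matrices, spec, config, k = k)
  path <- rfeCV(combined, config = config, minFeatures = minFeatures)
  opt <- optimalSubset(path, maxFeatures = maxFeatures,
                       accuracyFloor = accuracyFloor)
  lab <- .subunitLabels(spec$genes)
  feats <- opt$featureSet@features
  opt$featureSet@provenance <- "complex"
  list(combined = combined, path = path, optimal = opt,
       subunitFeatures = paste0(lab[feats$gene], "-", feats$ap))
}
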