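#' Run the full per-gene classification screen
#'
#' For every gene: encode the alignment, evaluate the full-length (v1)
#' model by repeated-subsampling CV, extract the ten strongest features
#' from a single full-data fit and evaluate them (v2), then run the
#' recursive feature elimination from the full-length alignment and
#' extract the optimal set of at most \code{maxFeatures} features (v3).
#' Genes with fewer columns than \code{minFeatures} are reported with v1
#' metrics only and flagged.  The report is deterministic given the
#' alignments and the config's master seed.
#'
#' @param alignments named list of labeled [LabeledAlignment-class]
#'   objects sharing the same samples and labels
#' @param config a [cvConfig()]
#' @param maxFeatures v3 feature budget (default 10)
#' @param minFeatures smallest RFE set (default 2)
#' @param accuracyFloor optimal-zone accuracy threshold (default 0.9)
#' @param rfeFrom \code{"full"} starts the elimination from the
#'   full-length alignment (canonical); \code{"v2"} starts from the ten
#'   strongest features (cheaper, non-canonical)
#' @param genesForRFE optional character vector restricting the v3 stage
#'   to a gene subset (v1/v2 always run for all genes)
#' @param keys optional named list of [ColumnKeys-class] overriding the
#'   per-gene encodings (for encoding-robustness checks)
#' @return a [ScreenReport-class]
#' @export
screenGenes <- function(alignments, config = cvConfig(),
                        maxFeatures = 10L, minFeatures = 2L,
                        accuracyFloor = 0.9,
                        rfeFrom = c("full", "v2"), genesForRFE = NULL,
                        keys = NULL) {
  rfeFrom <- match.arg(rfeFrom)
  if (!length(alignments)) stop("no alignments supplied")
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, geneName, "")
  ids <- sampleIds(alignments[[1L]])
  lab <- unname(phenoLabels(alignments[[1L]]))
  for (g in names(alignments)) {
    a <- alignments[[g]]
    if (!identical(sampleIds(a), ids))
      stop("sample-set mismatch at gene '", g, "'")
    if (!identical(unname(phenoLabels(a)), lab))
      stop("label mismatch at gene '", g, "'")
  }
  if (!length(lab)) stop("alignments are unlabeled")
  paths <- cvs <- optimal <- refMaps <- list()
  rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    fm <- if (!is.null(keys) && !is.null(keys[[g]]))
      encodeAlignment(aln, keys[[g]]) else encodeAlignment(aln)
    v1 <- repeatedSubsampleCV(fm, config = config)
    coefs <- fullDataCoefficients(fm, config = config)
    v2set <- strongestKFeatures(coefs, k = maxFeatures,
                                meta = columnMeta(fm))
    v2 <- repeatedSubsampleCV(selectFeatures(fm, v2set), config = config)
    row <- data.frame(gene = g, nColumns = ncol(as.matrix(fm)),
                      v1_accuracy = cvMeans(v1)[["accuracy"]],
                      v1_auroc = cvMeans(v1)[["auroc"]],
                      v2_features = paste(v2set@features$ap,
                                          collapse = ","),
                      v2_accuracy = cvMeans(v2)[["accuracy"]],
                      v2_auroc = cvMeans(v2)[["auroc"]])
    cvs[[g]] <- list(v1 = v1, v2 = v2)
    doRFE <- ncol(as.matrix(fm)) >= minFeatures &&
      (is.null(genesForRFE) || g %in% genesForRFE)
    if (doRFE) {
      start <- if (rfeFrom == "full") fm else selectFeatures(fm, v2set)
      path <- rfeCV(start, config = config, minFeatures = minFeatures)
      opt <- optimalSubset(path, maxFeatures = maxFeatures,
                           accuracyFloor = accuracyFloor)
      v3 <- repeatedSubsampleCV(selectFeatures(fm, opt$featureSet),
                                config = config)
      refStr <- NA_character_
      if (!is.na(referenceId(aln))) {
        map <- buildReferenceMap(aln)
        refMaps[[g]] <- map
        rp <- map$refPos[match(opt$featureSet@features$ap, map$ap)]
        refStr <- paste(ifelse(is.na(rp), "unmapped", rp),
                        collapse = ",")
      }
      row <- cbind(row, data.frame(
        v3_n_features = opt$nFeatures,
        v3_features = paste(opt$featureSet@features$ap, collapse = ","),
        v3_ref_positions = refStr,
        v3_roc_auc = opt$metrics[["auroc"]],
        v3_precision = opt$metrics[["precision"]],
        v3_recall = opt$metrics[["recall"]],
        v3_f1 = opt$metrics[["f1"]],
        v3_accuracy = opt$metrics[["accuracy"]],
        in_zone = opt$inZone, flagged_v1_only = FALSE))
      paths[[g]] <- path
      optimal[[g]] <- opt$featureSet
      cvs[[g]]$v3 <- v3
    } else {
      row <- cbind(row, data.frame(
        v3_n_features = NA_integer_, v3_features = NA_character_,
        v3_ref_positions = NA_character_, v3_roc_auc = NA_real_,
        v3_precision = NA_real_, v3_recall = NA_real_,
        v3_f1 = NA_real_, v3_accuracy = NA_real_, in_zone = NA,
        flagged_v1_only = ncol(as.matrix(fm)) < minFeatures))
    }
    rows[[g]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("ScreenReport", table = tab, paths = paths, cvs = cvs,
      optimal = optimal, referenceMaps = refMaps,
      config = unclass(config))
}

#' Compare top-ranking models against the 80th-percentile model
#'
#' Implements the "better than 80 percent of models" check: the comparator
#' gene is the one sitting at the given percentile of the v1
#' mean-accuracy ranking, and each gene ranked above it is compared to it
#' with a two-sample Student's t-test on the per-iteration accuracies,
#' Bonferroni-corrected over the number of comparisons.
#'
#' @param report a [ScreenReport-class]
#' @param percentile rank quantile of the comparator (default 0.8)
#' @param metric per-iteration metric to compare
#' @param alpha significance level on the adjusted p
#' @return data.frame, one row per gene above the percentile
#' @export
compareTopToPercentile <- function(report, percentile = 0.8,
                                   metric = "accuracy", alpha = 0.001) {
  stopifnot(is(report, "ScreenReport"))
  acc <- setNames(report@table$v1_accuracy, report@table$gene)
  ord <- names(sort(acc))
  compIdx <- max(1L, ceiling(percentile * length(ord)))
  comparator <- ord[compIdx]
  tops <- ord[seq_along(ord) > compIdx]
  if (!length(tops)) stop("no gene ranks above the percentile")
  m <- length(tops)
  ref <- cvIterations(report@cvs[[comparator]]$v1)[[metric]]
  do.call(rbind, lapply(tops, function(g) {
    cmp <- compareMetricDistributions(
      cvIterations(report@cvs[[g]]$v1)[[metric]], ref,
      alpha = alpha, m = m)
    cbind(data.frame(gene = g, comparator = comparator), cmp)
  }))
}

#' Permutation-label null battery
#'
#' Runs [permutedLabelCV()] for every gene and, when the true-label
#' report is supplied, compares true against permuted per-iteration
#' accuracy and AUROC with Student's t-tests, Bonferroni-corrected over
#' the number of genes.
#'
#' @param alignments named list of labeled [LabeledAlignment-class]
#' @param config a [cvConfig()]
#' @param report optional [ScreenReport-class] from [screenGenes()] on
#'   the same data and config
#' @param alpha significance level on the adjusted p
#' @param keys optional per-gene [ColumnKeys-class] overrides
#' @return list with \code{table} (per-gene null means and comparison
#'   results) and \code{cvs} (the null [CVSummary-class] objects)
#' @export
runNullBattery <- function(alignments, config = cvConfig(),
                           report = NULL, alpha = 0.001, keys = NULL) {
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, geneName, "")
  m <- length(alignments)
  cvs <- list()
  rows <- lapply(names(alignments), function(g) {
    fm <- if (!is.null(keys) && !is.null(keys[[g]]))
      encodeAlignment(alignments[[g]], keys[[g]])
      else encodeAlignment(alignments[[g]])
    null <- permutedLabelCV(fm, config = config)
    cvs[[g]] <<- null
    row <- data.frame(gene = g,
                      null_accuracy = cvMeans(null)[["accuracy"]],
                      null_auroc = cvMeans(null)[["auroc"]])
    if (!is.null(report)) {
      v1 <- report@cvs[[g]]$v1
      ca <- compareMetricDistributions(v1, null, alpha = alpha, m = m,
                                       metric = "accuracy")
      cu <- compareMetricDistributions(v1, null, alpha = alpha, m = m,
                                       metric = "auroc")
      row <- cbind(row, data.frame(
        accuracy_t = ca$statistic, accuracy_adj_p = ca$adjustedP,
        accuracy_significant = ca$significant,
        auroc_t = cu$statistic, auroc_adj_p = cu$adjustedP,
        auroc_significant = cu$significant))
    }
    row
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, cvs = cvs)
}

#' Write screen report files
#'
#' \code{screen_report.tsv} (the per-gene table) and
#' \code{rfe_paths.json}; optionally \code{null_report.tsv} when a null
#' battery is supplied.  Output is byte-identical under a fixed master
#' seed.
#'
#' @param report a [ScreenReport-class]
#' @param dir output directory (created if needed)
#' @param null optional result of [runNullBattery()]
#' @return invisibly, the paths written
#' @export
writeScreenReport <- function(report, dir, null = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "screen_report.tsv")
  utils::write.table(report@table, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, "rfe_paths.json")
  writeLines(jsonlite::toJSON(
    lapply(report@paths, function(p)
      list(featureIds = p@featureIds, steps = p@steps)),
    auto_unbox = TRUE, na = "null", digits = NA), p2)
  paths <- c(p1, p2)
  if (!is.null(null)) {
    p3 <- file.path(dir, "null_report.tsv")
    utils::write.table(null$table, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
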