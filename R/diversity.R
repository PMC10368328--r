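#' Mean pairwise distance of an alignment
#'
#' The average, over all unordered sequence pairs, of the number of
#' columns at which the two sequences differ.  A gap compared with a
#' residue counts as a difference; two gaps count as identical (shared
#' gaps carry no divergence information).  Comparison is
#' case-insensitive.  Computed per column from character counts
#' (\eqn{\binom{n}{2} - \sum_c \binom{n_c}{2}} differing pairs), which is
#' exactly the mean of the pairwise Hamming-style counts.
#'
#' @param aln a [LabeledAlignment-class]
#' @param subset optional sample filter: sample ids, a logical vector, or
#'   a label value (e.g. \code{"C3"} to use only class-0 sequences)
#' @return one-row data.frame: \code{gene}, \code{subset}, \code{nSeqs},
#'   \code{length}, \code{mpd}, \code{mpdPer100} (\code{mpd * 100 /
#'   length})
#' @examples
#' aln <- LabeledAlignment(c(a = "AAA", b = "AAT", d = "ATT"), "toy")
#' meanPairwiseDistance(aln)$mpd  # 4/3
#' @export
meanPairwiseDistance <- function(aln, subset = NULL) {
  stopifnot(is(aln, "LabeledAlignment"))
  m <- as.matrix(aln)
  subsetName <- "all"
  if (!is.null(subset)) {
    if (is.logical(subset)) {
      keep <- subset
      subsetName <- "logical"
    } else if (all(subset %in% rownames(m))) {
      keep <- rownames(m) %in% subset
      subsetName <- "ids"
    } else if (length(subset) == 1L && length(aln@labels) &&
               subset %in% aln@labels) {
      keep <- aln@labels == subset
      subsetName <- as.character(subset)
    } else stop("cannot resolve 'subset'")
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2L) stop("MPD needs >= 2 sequences after subsetting")
  m <- toupper(m)
  npairs <- n * (n - 1) / 2
  diffpairs <- vapply(seq_len(ncol(m)), function(j) {
    cnt <- as.integer(table(m[, j]))
    npairs - sum(cnt * (cnt - 1) / 2)
  }, numeric(1))
  mpd <- sum(diffpairs) / npairs
  data.frame(gene = aln@gene, subset = subsetName, nSeqs = n,
             length = ncol(m), mpd = mpd,
             mpdPer100 = mpd * 100 / ncol(m))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] enforcing the contract needed for
#' the accuracy-correlation analyses: equal lengths of at least 3 and no
#' constant input.
#'
#' @param x,y numeric vectors
#' @return r in \[-1, 1\]
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input")
  stats::cor(x, y, method = "pearson")
}

#' Correlate alignment diversity with model accuracy
#'
#' Pearson correlations of per-gene optimal-model accuracy with mean
#' pairwise distance, alignment length, and length-normalized MPD
#' (per 100 residues).  MPD is conventionally computed on the class-0
#' (e.g. C3) sequences only, so variation caused by the phenotype
#' transitions themselves does not enter the diversity measure; pass
#' records built with the wanted subset.
#'
#' @param records data.frame of per-gene rows as returned by
#'   [meanPairwiseDistance()] (rbind-ed)
#' @param accuracies named numeric vector of per-gene accuracies
#' @return list with \code{correlations} (data.frame of the three r
#'   values) and \code{table} (scatter-ready merged per-gene data)
#' @export
accuracyCorrelates <- function(records, accuracies) {
  genes <- intersect(records$gene, names(accuracies))
  if (length(genes) < 3L) stop("need >= 3 genes in common")
  rec <- records[match(genes, records$gene), , drop = FALSE]
  acc <- as.numeric(accuracies[genes])
  tab <- data.frame(gene = genes, accuracy = acc, mpd = rec$mpd,
                    length = rec$length, mpdPer100 = rec$mpdPer100)
  corr <- data.frame(
    predictor = c("mpd", "length", "mpdPer100"),
    r = c(pearsonR(tab$mpd, acc), pearsonR(tab$length, acc),
          pearsonR(tab$mpdPer100, acc)))
  list(correlations = corr, table = tab)
}
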