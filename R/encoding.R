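#' Build per-column ordinal encoding keys
#'
#' Each alignment column gets a key mapping every character observed in it
#' (amino-acid letters, ambiguity letters, the gap \code{"-"}) to an
#' integer code in \code{0..N-1}, N being the number of distinct
#' characters.  Codes follow descending character frequency, ties broken
#' alphabetically, so most columns are binary \code{0/1} with 0 the modal
#' state.  Class labels play no part, so the keys can be built once on the
#' full dataset without leaking label information into cross-validation.
#'
#' @param aln a [LabeledAlignment-class]
#' @return a [ColumnKeys-class]
#' @export
buildColumnKeys <- function(aln) {
  stopifnot(is(aln, "LabeledAlignment"))
  m <- as.matrix(aln)
  keys <- lapply(seq_len(ncol(m)), function(j) {
    tb <- table(m[, j])
    chars <- names(tb)[order(-as.integer(tb), names(tb))]
    setNames(seq_along(chars) - 1L, chars)
  })
  new("ColumnKeys", gene = aln@gene, ap = seq_len(ncol(m)), keys = keys)
}

#' Encode an alignment as an integer feature matrix
#'
#' Applies per-column keys to produce the samples x columns ordinal
#' feature matrix used by all downstream classifiers.  Column metadata
#' carries \code{(gene, ap)}; labels are copied through.
#'
#' @param aln a [LabeledAlignment-class]
#' @param keys a [ColumnKeys-class]; defaults to keys freshly built from
#'   \code{aln}
#' @return a [FeatureMatrix-class]
#' @export
encodeAlignment <- function(aln, keys = buildColumnKeys(aln)) {
  stopifnot(is(aln, "LabeledAlignment"), is(keys, "ColumnKeys"))
  m <- as.matrix(aln)
  if (ncol(m) != length(keys@keys))
    stop("encoding error: keys cover ", length(keys@keys),
         " columns but alignment has ", ncol(m))
  vals <- matrix(0L, nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) {
    k <- keys@keys[[j]]
    code <- k[m[, j]]
    if (anyNA(code)) {
      i <- which(is.na(code))[1L]
      stop("encoding error: character '", m[i, j], "' of sample '",
           rownames(m)[i], "' has no code at ap ", keys@ap[j])
    }
    vals[, j] <- as.integer(code)
  }
  rownames(vals) <- rownames(m)
  colnames(vals) <- paste0(aln@gene, ":", keys@ap)
  new("FeatureMatrix", values = vals,
      columnMeta = data.frame(gene = aln@gene, ap = keys@ap),
      labels = aln@labels)
}

#' Decode a feature matrix back into sequences
#'
#' Inverts [encodeAlignment()] through the per-column key bijections;
#' useful mostly as an integrity check.
#'
#' @param fm a [FeatureMatrix-class]
#' @param keys the [ColumnKeys-class] used to encode it
#' @return character vector of sequences named by sample id
#' @export
decodeAlignment <- function(fm, keys) {
  stopifnot(is(fm, "FeatureMatrix"), is(keys, "ColumnKeys"))
  v <- fm@values
  chars <- vapply(seq_len(ncol(v)), function(j) {
    k <- keys@keys[[j]]
    names(k)[match(v[, j], k)]
  }, character(nrow(v)))
  if (nrow(v) == 1L) chars <- matrix(chars, nrow = 1L)
  setNames(apply(chars, 1L, paste0, collapse = ""), rownames(v))
}

#' Permute encoding keys for robustness checks
#'
#' Re-labels column codes to probe whether downstream screening depends on
#' the arbitrary code assignment.  \code{"swap-binary"} exchanges codes
#' \code{0 <-> 1} in a seeded random subset of columns of the given
#' \code{fraction} (columns with more than two states get a seeded
#' transposition of two of their codes); \code{"full-shuffle"} replaces
#' every column's assignment with a seeded random permutation of
#' \code{0..N-1} (\code{fraction} is ignored).
#'
#' @param keys a [ColumnKeys-class]
#' @param fraction proportion of columns to swap (swap-binary mode)
#' @param mode \code{"swap-binary"} or \code{"full-shuffle"}
#' @param seed integer seed; identical seeds give identical permutations
#' @return a [ColumnKeys-class]
#' @export
permuteKeys <- function(keys, fraction = 0.5,
                        mode = c("swap-binary", "full-shuffle"),
                        seed = 1L) {
  stopifnot(is(keys, "ColumnKeys"), fraction >= 0, fraction <= 1)
  mode <- match.arg(mode)
  nc <- length(keys@keys)
  out <- keys@keys
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  if (mode == "swap-binary") {
    pick <- sample.int(nc, size = round(fraction * nc))
    for (j in pick) {
      k <- out[[j]]
      n <- length(k)
      if (n < 2L) next
      ij <- if (n == 2L) c(1L, 2L) else sample.int(n, 2L)
      tmp <- k[ij[1L]]
      k[ij[1L]] <- k[ij[2L]]
      k[ij[2L]] <- tmp
      out[[j]] <- k
    }
  } else {
    for (j in seq_len(nc)) {
      k <- out[[j]]
      n <- length(k)
      if (n < 2L) next
      out[[j]] <- setNames(sample(0:(n - 1L)), names(k))
    }
  }
  new("ColumnKeys", gene = keys@gene, ap = keys@ap, keys = out)
}

#' Serialize column keys to JSON
#'
#' One record per column: \code{\{gene, ap, mapping\}}.
#'
#' @param keys a [ColumnKeys-class]
#' @param path optional file; when omitted the JSON string is returned
#' @return the JSON string (invisibly when written to file)
#' @export
keysToJSON <- function(keys, path = NULL) {
  recs <- lapply(seq_along(keys@keys), function(j)
    list(gene = keys@gene, ap = keys@ap[j],
         mapping = as.list(keys@keys[[j]])))
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Export a feature matrix as TSV
#'
#' Writes a two-row header (gene, then ap) above the per-sample integer
#' rows, first column \code{sample_id}, optional second column
#' \code{label}.
#'
#' @param fm a [FeatureMatrix-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeFeatureMatrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hasLab <- length(fm@labels) > 0L
  pre <- if (hasLab) c("sample_id", "label") else "sample_id"
  writeLines(paste(c(pre[1], if (hasLab) "", fm@columnMeta$gene),
                   collapse = "\t"), con)
  writeLines(paste(c("ap", if (hasLab) "", fm@columnMeta$ap),
                   collapse = "\t"), con)
  v <- fm@values
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], if (hasLab) fm@labels[i], v[i, ]),
                     collapse = "\t"), con)
  invisible(path)
}

#' Subset a feature matrix by feature ids
#'
#' @param fm a [FeatureMatrix-class]
#' @param ids feature ids (\code{"gene:ap"}) or a [FeatureSet-class]
#' @return a [FeatureMatrix-class] restricted to those columns, in the
#'   requested order
#' @export
selectFeatures <- function(fm, ids) {
  if (is(ids, "FeatureSet")) ids <- featureIds(ids)
  j <- match(ids, colnames(fm@values))
  if (anyNA(j))
    stop("unknown feature id(s): ", paste(ids[is.na(j)], collapse = ", "))
  new("FeatureMatrix", values = fm@values[, j, drop = FALSE],
      columnMeta = fm@columnMeta[j, , drop = FALSE], labels = fm@labels)
}
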