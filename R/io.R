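#' Construct a LabeledAlignment
#'
#' @param seqs an [Biostrings::AAStringSet] or named character vector of
#'   equal-length gapped amino-acid sequences
#' @param gene gene name
#' @param labels optional per-sample phenotype labels (at most two values)
#' @param groups optional data.frame of per-sample annotations
#' @param referenceId optional sample id used for coordinate renumbering
#' @return a [LabeledAlignment-class]
#' @export
LabeledAlignment <- function(seqs, gene, labels = NULL, groups = NULL,
                             referenceId = NULL) {
  if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  new("LabeledAlignment", gene = as.character(gene), seqs = seqs,
      labels = if (is.null(labels)) character(0) else as.character(labels),
      groups = if (is.null(groups)) data.frame() else as.data.frame(groups),
      referenceId = if (is.null(referenceId)) character(0)
                    else as.character(referenceId))
}

#' Read a gapped protein alignment from FASTA
#'
#' Rows are uppercased; record order is preserved.  At least two records
#' are required (pairwise statistics and classification are undefined on a
#' single sequence) and all rows must have equal length.
#'
#' @param path FASTA file of aligned (gapped) amino-acid sequences
#' @param gene gene name attached to the alignment
#' @return an unlabeled [LabeledAlignment-class]
#' @export
readAlignment <- function(path, gene) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("input error: no FASTA records in ", path)
  if (length(seqs) < 2L)
    stop("input error: alignment needs >= 2 records, got ", length(seqs))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("input error: duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment-shape error: ragged row lengths (",
         paste(range(w), collapse = "-"), ") in ", path)
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  LabeledAlignment(seqs, gene = gene)
}

#' Write an alignment to FASTA
#' @param aln a [LabeledAlignment-class]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln@seqs, path, width = 80L)
  invisible(path)
}

#' Read a sample label table
#'
#' Tab-separated with header \code{sample_id<TAB>label[<TAB>group...]}.
#'
#' @param path TSV file
#' @return data.frame with at least \code{sample_id} and \code{label}
#' @export
readLabelTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(tab)))
    stop("input error: label table needs 'sample_id' and 'label' columns")
  tab
}

#' Attach phenotype labels (and optional groups) to an alignment
#'
#' Every sample must be covered by the table; samples missing from it are
#' an error unless \code{dropUnlabeled = TRUE}, in which case they are
#' removed from the alignment.  The labels of the retained samples must
#' take at most two distinct values.
#'
#' @param aln a [LabeledAlignment-class]
#' @param table a data.frame as from [readLabelTable()] (or a path to one);
#'   columns beyond \code{sample_id} and \code{label} become group
#'   annotations
#' @param dropUnlabeled drop samples absent from the table instead of
#'   failing
#' @return a labeled [LabeledAlignment-class]
#' @export
attachLabels <- function(aln, table, dropUnlabeled = FALSE) {
  stopifnot(is(aln, "LabeledAlignment"))
  if (is.character(table) && length(table) == 1L)
    table <- readLabelTable(table)
  if (anyDuplicated(table$sample_id))
    stop("input error: duplicate sample_id in label table")
  ids <- sampleIds(aln)
  miss <- setdiff(ids, table$sample_id)
  if (length(miss)) {
    if (!dropUnlabeled)
      stop("input error: samples missing from label table: ",
           paste(miss, collapse = ", "))
    keep <- ids %in% table$sample_id
    aln@seqs <- aln@seqs[keep]
    if (nrow(aln@groups)) aln@groups <- aln@groups[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  i <- match(ids, table$sample_id)
  lab <- table$label[i]
  if (length(unique(lab)) > 2L)
    stop("input error: phenotype must be binary; found labels: ",
         paste(unique(lab), collapse = ", "))
  aln@labels <- as.character(lab)
  extra <- setdiff(names(table), c("sample_id", "label"))
  if (length(extra)) {
    g <- table[i, extra, drop = FALSE]
    rownames(g) <- ids
    aln@groups <- g
  }
  validObject(aln)
  aln
}

#' Set the reference sample of an alignment
#' @param x a [LabeledAlignment-class]
#' @param value a sample id
#' @return the modified object
#' @export
`referenceId<-` <- function(x, value) {
  x@referenceId <- as.character(value)
  validObject(x)
  x
}

#' Translate a plastid coding sequence
#'
#' Standard translation under NCBI genetic code 11 (bacterial, archaeal
#' and plant plastid).  A single terminal stop codon is stripped; internal
#' stop codons are an error naming the codon index.  There is no
#' start-codon special-casing: internal fidelity only.  Ambiguity
#' nucleotides are resolved where the codon is unambiguous at the protein
#' level and otherwise yield \code{"X"}.
#'
#' @param nuc a nucleotide string (IUPAC DNA/RNA alphabet)
#' @param tableId NCBI genetic code id (default 11, the plant plastid code)
#' @param trim allow a trailing partial codon, which is dropped
#' @return the amino-acid string
#' @examples
#' translateCDS("ATGGCTTCT")  # "MAS"
#' translateCDS("ATGGCTTAA")  # "MA", terminal stop stripped
#' @export
translateCDS <- function(nuc, tableId = 11, trim = FALSE) {
  stopifnot(is.character(nuc), length(nuc) == 1L)
  s <- toupper(gsub("U", "T", toupper(nuc), fixed = TRUE))
  bad <- gsub("[ACGTMRWSYKVHDBN]", "", s)
  if (nzchar(bad))
    stop("input error: non-IUPAC nucleotide character(s): ",
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ", "))
  r <- nchar(s) %% 3L
  if (r != 0L) {
    if (!trim)
      stop("input error: CDS length ", nchar(s),
           " is not divisible by 3 (set trim = TRUE to drop the tail)")
    s <- substr(s, 1L, nchar(s) - r)
  }
  if (nchar(s) == 0L) return("")
  code <- Biostrings::getGeneticCode(as.character(tableId))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(s), genetic.code = code,
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  stops <- which(strsplit(aa, "")[[1L]] == "*")
  ncod <- nchar(aa)
  if (any(stops < ncod))
    stop("translation error: internal stop codon at codon ",
         stops[stops < ncod][1L])
  if (length(stops) && stops[length(stops)] == ncod)
    aa <- substr(aa, 1L, ncod - 1L)
  aa
}

#' Map alignment positions to reference residue numbering
#'
#' Numbers each 1-based alignment position (ap) by the cumulative count of
#' non-gap characters in the reference row; positions where the reference
#' row has a gap are unmapped (\code{NA}) and are reported as such, never
#' silently shifted.
#'
#' @param aln a [LabeledAlignment-class] with \code{referenceId} set
#' @return data.frame with columns \code{gene}, \code{ap}, \code{refPos}
#'   (\code{NA} = unmapped)
#' @examples
#' aln <- LabeledAlignment(c(ref = "M-KT", s2 = "MAKT"), "g",
#'                         referenceId = "ref")
#' buildReferenceMap(aln)  # refPos 1, NA, 2, 3
#' @export
buildReferenceMap <- function(aln) {
  stopifnot(is(aln, "LabeledAlignment"))
  if (!length(aln@referenceId))
    stop("input error: no referenceId set on alignment '", aln@gene, "'")
  row <- strsplit(as.character(aln@seqs[[aln@referenceId]]), "")[[1L]]
  nongap <- row != "-"
  refPos <- ifelse(nongap, cumsum(nongap), NA_integer_)
  data.frame(gene = aln@gene, ap = seq_along(row),
             refPos = as.integer(refPos))
}

#' Write a reference map as TSV
#'
#' Columns \code{gene}, \code{ap}, \code{ref_pos}; unmapped positions are
#' written as the literal string \code{"unmapped"}.
#'
#' @param map data.frame from [buildReferenceMap()]
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeReferenceMap <- function(map, path) {
  out <- data.frame(gene = map$gene, ap = map$ap,
                    ref_pos = ifelse(is.na(map$refPos), "unmapped",
                                     as.character(map$refPos)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
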