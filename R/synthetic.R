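#' Specification of a synthetic screen dataset
#'
#' Describes a labeled, lineage-structured alignment dataset with planted
#' convergent signal columns.  Defaults mirror the structure of the real
#' screen data: 58 class-0 and 76 class-1 samples, the class-1 samples
#' partitioned into 16 independent lineage blocks (independent phenotype
#' origins), per-gene alignments of a few hundred mostly binary columns.
#' Background columns are i.i.d. across samples and independent of the
#' labels; lineage structure enters only through where signal is planted.
#'
#' @param genes list of per-gene specs from [geneSpec()]
#' @param nClass0,nClass1 sample counts per class
#' @param nLineages number of class-1 lineage blocks
#' @param labels the two phenotype labels, class 0 first
#' @param pInvariant probability a background column is invariant
#' @param pGap probability a background column carries gaps as its minor
#'   state
#' @param pMultistate probability a background column has three character
#'   states
#' @param minorFreqRange uniform range of the minor-state frequency of
#'   variable background columns
#' @param ambiguityRate per-cell rate at which background-column residues
#'   are replaced by the ambiguity letter \code{"X"} (0 disables)
#' @return list of class \code{"syntheticSpec"}
#' @export
syntheticSpec <- function(genes, nClass0 = 58L, nClass1 = 76L,
                          nLineages = 16L, labels = c("C3", "C4"),
                          pInvariant = 0.55, pGap = 0.03,
                          pMultistate = 0.05,
                          minorFreqRange = c(0.02, 0.45),
                          ambiguityRate = 0) {
  stopifnot(length(labels) == 2L, nClass0 >= 2L, nClass1 >= 2L,
            nLineages >= 1L)
  nm <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate gene names in spec")
  structure(list(genes = setNames(genes, nm),
                 nClass0 = as.integer(nClass0),
                 nClass1 = as.integer(nClass1),
                 nLineages = as.integer(nLineages), labels = labels,
                 pInvariant = pInvariant, pGap = pGap,
                 pMultistate = pMultistate,
                 minorFreqRange = minorFreqRange,
                 ambiguityRate = ambiguityRate),
            class = "syntheticSpec")
}

#' Per-gene part of a synthetic specification
#'
#' @param name gene name
#' @param length alignment length in columns
#' @param nSignal number of planted phenotype-associated columns
#' @param penetrance probability \code{q} that a class-1 sample in a
#'   signal-bearing lineage carries the alternative residue
#' @param mLineages number of lineages carrying the signal at each planted
#'   column
#' @param leakage probability a class-0 sample carries the alternative
#'   residue
#' @param signalResidues optional list of \code{c(class0, class1)} residue
#'   pairs, one per signal column; the two residues must differ
#' @return a list consumed by [syntheticSpec()]
#' @export
geneSpec <- function(name, length, nSignal = 0L, penetrance = 0.9,
                     mLineages = 16L, leakage = 0.02,
                     signalResidues = NULL) {
  stopifnot(length >= nSignal, penetrance >= 0, penetrance <= 1,
            leakage >= 0, leakage <= 1)
  if (!is.null(signalResidues)) {
    for (p in signalResidues)
      if (p[1] == p[2])
        stop("signal residues identical for the two classes: ", p[1])
  }
  list(name = as.character(name), length = as.integer(length),
       nSignal = as.integer(nSignal), penetrance = penetrance,
       mLineages = as.integer(mLineages), leakage = leakage,
       signalResidues = signalResidues)
}

#' The default synthetic screen scenario
#'
#' One strong-signal gene (RbcL-like: 475 columns, six planted columns of
#' penetrance 0.9 across 13 of 16 lineages, 2\% class-0 leakage), one
#' moderate-signal gene, and eight pure-noise genes with lengths spanning
#' 100-800 columns.
#'
#' @return a [syntheticSpec()]
#' @export
defaultScreenSpec <- function() {
  nulls <- Map(function(i, L) geneSpec(paste0("null", i), L),
               1:8, c(100L, 180L, 260L, 340L, 420L, 500L, 640L, 800L))
  syntheticSpec(c(list(
    geneSpec("rbcl_like", 475L, nSignal = 6L, penetrance = 0.9,
             mLineages = 13L, leakage = 0.02),
    geneSpec("ndh_like", 360L, nSignal = 3L, penetrance = 0.6,
             mLineages = 8L, leakage = 0.05)), nulls))
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Assign samples to phenotype lineages
#'
#' Class-1 samples are partitioned into \code{nLineages} non-empty blocks
#' with sizes as even as possible (emulating independent phenotype
#' origins); class-0 samples get sister-lineage tags distributed
#' round-robin.  Deterministic given \code{(spec, seed)}.
#'
#' @param spec a [syntheticSpec()]
#' @param seed integer seed
#' @return data.frame with \code{sampleId}, \code{label}, \code{lineage}
#' @export
generateLineages <- function(spec, seed = 1L) {
  if (spec$nClass1 < spec$nLineages)
    stop("nClass1 (", spec$nClass1, ") < nLineages (", spec$nLineages, ")")
  id0 <- sprintf("%s_%03d", tolower(spec$labels[1]), seq_len(spec$nClass0))
  id1 <- sprintf("%s_%03d", tolower(spec$labels[2]), seq_len(spec$nClass1))
  .withSeed(seed, {
    nl <- spec$nLineages
    base <- spec$nClass1 %/% nl
    sizes <- rep(base, nl) + c(rep(1L, spec$nClass1 %% nl),
                               rep(0L, nl - spec$nClass1 %% nl))
    lin1 <- rep(sprintf("L%02d", seq_len(nl)), times = sizes)
    lin1 <- lin1[sample.int(length(lin1))]
    lin0 <- sprintf("L%02d_sister",
                    rep(seq_len(nl), length.out = spec$nClass0))
    lin0 <- lin0[sample.int(length(lin0))]
    data.frame(sampleId = c(id0, id1),
               label = rep(spec$labels, c(spec$nClass0, spec$nClass1)),
               lineage = c(lin0, lin1))
  })
}

#' Generate a synthetic labeled alignment dataset with planted signal
#'
#' Background columns are drawn per the spec's background parameters
#' (invariant, binary with a drawn minor frequency, occasionally
#' three-state or gapped), independently of the labels.  Each planted
#' signal column gives class-0 samples the consensus residue except for a
#' leakage fraction, and gives class-1 samples in \code{mLineages}
#' seeded-chosen lineages the alternative residue with probability
#' \code{penetrance} (others the consensus) - lineage-restricted,
#' partially penetrant convergent signal.  Ground truth, including the
#' realized class-conditional residue frequencies, is recorded.
#'
#' @param spec a [syntheticSpec()]
#' @param seed integer seed; identical \code{(spec, seed)} give
#'   byte-identical output
#' @return list with \code{alignments} (named list of labeled
#'   [LabeledAlignment-class], lineage as group annotation) and
#'   \code{truth} (a [SyntheticTruth-class])
#' @export
generateDataset <- function(spec, seed = 1L) {
  lin <- generateLineages(spec, seed)
  n <- nrow(lin)
  is1 <- lin$label == spec$labels[2]
  alignments <- list()
  truthGenes <- list()
  .withSeed(seed + 1L, {
    for (gs in spec$genes) {
      if (gs$nSignal > 0L && gs$mLineages > spec$nLineages)
        stop("gene '", gs$name, "': mLineages (", gs$mLineages,
             ") exceeds nLineages (", spec$nLineages, ")")
      L <- gs$length
      m <- matrix("", n, L)
      sigAp <- if (gs$nSignal > 0L) sort(sample.int(L, gs$nSignal))
               else integer(0)
      # background columns (label-independent, i.i.d. across samples)
      for (j in setdiff(seq_len(L), sigAp)) {
        r <- runif(1)
        if (r < spec$pInvariant) {
          m[, j] <- sample(.AA20, 1L)
        } else if (r < spec$pInvariant + spec$pGap) {
          f <- runif(1, spec$minorFreqRange[1], spec$minorFreqRange[2])
          base <- sample(.AA20, 1L)
          m[, j] <- ifelse(runif(n) < f, "-", base)
        } else if (r < spec$pInvariant + spec$pGap + spec$pMultistate) {
          chars <- sample(.AA20, 3L)
          pr <- runif(3) + 0.15
          m[, j] <- sample(chars, n, replace = TRUE, prob = pr / sum(pr))
        } else {
          f <- runif(1, spec$minorFreqRange[1], spec$minorFreqRange[2])
          chars <- sample(.AA20, 2L)
          m[, j] <- ifelse(runif(n) < f, chars[2], chars[1])
        }
        if (spec$ambiguityRate > 0) {
          hit <- runif(n) < spec$ambiguityRate
          m[hit, j] <- "X"
        }
      }
      # planted signal columns
      truth <- NULL
      linNames <- sprintf("L%02d", seq_len(spec$nLineages))
      for (s in seq_along(sigAp)) {
        j <- sigAp[s]
        res <- if (!is.null(gs$signalResidues)) gs$signalResidues[[s]]
               else sample(.AA20, 2L)
        if (res[1] == res[2])
          stop("signal residues identical for the two classes: ", res[1])
        sigLin <- sort(sample(linNames, gs$mLineages))
        col <- rep(res[1], n)
        inSig <- is1 & lin$lineage %in% sigLin
        col[inSig] <- ifelse(runif(sum(inSig)) < gs$penetrance,
                             res[2], res[1])
        leak <- !is1 & runif(n) < gs$leakage
        col[leak] <- res[2]
        m[, j] <- col
        truth <- rbind(truth, data.frame(
          ap = j, class0Residue = res[1], class1Residue = res[2],
          mLineages = gs$mLineages, penetrance = gs$penetrance,
          leakage = gs$leakage,
          signalLineages = paste(sigLin, collapse = ","),
          realizedClass1AltFreq = mean(m[is1, j] == res[2]),
          realizedClass0AltFreq = mean(m[!is1, j] == res[2])))
      }
      seqs <- apply(m, 1L, paste0, collapse = "")
      names(seqs) <- lin$sampleId
      alignments[[gs$name]] <- LabeledAlignment(
        seqs, gene = gs$name, labels = lin$label,
        groups = data.frame(lineage = lin$lineage,
                            row.names = lin$sampleId))
      truthGenes[[gs$name]] <- if (is.null(truth)) data.frame() else truth
    }
  })
  list(alignments = alignments,
       truth = new("SyntheticTruth", genes = truthGenes, lineages = lin,
                   spec = unclass(spec)))
}

#' Verify a synthetic dataset against its recorded ground truth
#'
#' Recomputes the class-conditional alternative-residue frequencies at
#' every planted column and requires an exact match with the recorded
#' truth (an integrity error naming the column otherwise); additionally
#' screens all non-truth variable columns for label association with a
#' Bonferroni-corrected chi-square test, reporting any column whose
#' association is too strong to be background noise.
#'
#' @param alignments named list of [LabeledAlignment-class]
#' @param truth the matching [SyntheticTruth-class]
#' @param alpha family-wise error rate of the background screen
#' @return list with \code{ok}, \code{nCheckedTruth},
#'   \code{nCheckedBackground}, \code{flaggedColumns}
#' @export
verifyTruth <- function(alignments, truth, alpha = 0.001) {
  stopifnot(is(truth, "SyntheticTruth"))
  class1 <- truth@spec$labels[2]
  flagged <- character(0)
  nTruth <- 0L
  bgP <- numeric(0)
  bgId <- character(0)
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    m <- as.matrix(aln)
    is1 <- phenoLabels(aln) == class1
    tr <- truth@genes[[g]]
    tAp <- if (NROW(tr)) tr$ap else integer(0)
    for (i in seq_len(NROW(tr))) {
      f1 <- mean(m[is1, tr$ap[i]] == tr$class1Residue[i])
      f0 <- mean(m[!is1, tr$ap[i]] == tr$class1Residue[i])
      if (!isTRUE(all.equal(f1, tr$realizedClass1AltFreq[i])) ||
          !isTRUE(all.equal(f0, tr$realizedClass0AltFreq[i])))
        stop("integrity error: realized frequencies at ", g, ":",
             tr$ap[i], " do not match the recorded truth")
      nTruth <- nTruth + 1L
    }
    for (j in setdiff(seq_len(ncol(m)), tAp)) {
      if (length(unique(m[, j])) < 2L) next
      p <- suppressWarnings(
        stats::chisq.test(table(m[, j], is1))$p.value)
      bgP <- c(bgP, p)
      bgId <- c(bgId, paste0(g, ":", j))
    }
  }
  flagged <- bgId[bgP < alpha / max(1L, length(bgP))]
  list(ok = length(flagged) == 0L, nCheckedTruth = nTruth,
       nCheckedBackground = length(bgP), flaggedColumns = flagged)
}

#' Write a synthetic dataset to disk
#'
#' Per-gene FASTA alignments, a \code{labels.tsv} (sample_id, label,
#' lineage) and a \code{truth.json}.  Output is byte-identical for
#' identical \code{(spec, seed)}.
#'
#' @param dataset result of [generateDataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in names(dataset$alignments)) {
    p <- file.path(dir, paste0(g, ".fasta"))
    writeAlignment(dataset$alignments[[g]], p)
    paths <- c(paths, p)
  }
  lab <- file.path(dir, "labels.tsv")
  tab <- dataset$truth@lineages
  names(tab)[1] <- "sample_id"
  utils::write.table(tab, lab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tj <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(dataset$truth@genes, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA), tj)
  invisible(c(paths, lab, tj))
}
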