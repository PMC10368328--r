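smallSpec <- function(...) {
  syntheticSpec(list(geneSpec("sig", 60L, nSignal = 2L, penetrance = 1,
                              mLineages = 4L, leakage = 0),
                     geneSpec("noise", 40L)),
                nClass0 = 10L, nClass1 = 12L, nLineages = 4L, ...)
}

test_that("lineage assignment partitions class-1 as evenly as possible", {
  spec <- syntheticSpec(list(geneSpec("g", 10L)))
  lin <- generateLineages(spec, seed = 3)
  c4 <- lin[lin$label == "C4", ]
  sizes <- table(c4$lineage)
  expect_length(sizes, 16L)
  expect_true(all(sizes %in% 4:5))         # 76 across 16 lineages
  expect_equal(sum(sizes), 76L)
  expect_equal(sum(lin$label == "C3"), 58L)
  # determinism and seed sensitivity
  expect_identical(generateLineages(spec, seed = 3), lin)
  expect_false(identical(generateLineages(spec, seed = 4), lin))
  # single lineage degenerate case
  one <- syntheticSpec(list(geneSpec("g", 10L)), nLineages = 1L)
  lin1 <- generateLineages(one, seed = 1)
  expect_equal(unique(lin1$lineage[lin1$label == "C4"]), "L01")
  expect_error(generateLineages(
    syntheticSpec(list(geneSpec("g", 5L)), nClass1 = 5L,
                  nLineages = 10L), 1), "nLineages")
})

test_that("generated datasets are deterministic down to the bytes", {
  d1 <- generateDataset(smallSpec(), seed = 11)
  d2 <- generateDataset(smallSpec(), seed = 11)
  dirA <- withr::local_tempdir()
  dirB <- withr::local_tempdir()
  writeDataset(d1, dirA)
  writeDataset(d2, dirB)
  for (f in list.files(dirA))
    expect_identical(readLines(file.path(dirA, f)),
                     readLines(file.path(dirB, f)),
                     label = f)
  d3 <- generateDataset(smallSpec(), seed = 12)
  expect_false(identical(as.character(d1$alignments$sig@seqs),
                         as.character(d3$alignments$sig@seqs)))
})

test_that("a fully penetrant unleaky column separates the classes", {
  spec <- syntheticSpec(list(
    geneSpec("g", 30L, nSignal = 1L, penetrance = 1, mLineages = 4L,
             leakage = 0)),
    nClass0 = 12L, nClass1 = 12L, nLineages = 4L)
  ds <- generateDataset(spec, seed = 5)
  tr <- ds$truth@genes$g
  m <- as.matrix(ds$alignments$g)
  isC4 <- phenoLabels(ds$alignments$g) == "C4"
  expect_identical(unname(m[, tr$ap] == tr$class1Residue), unname(isC4))
  expect_equal(tr$realizedClass1AltFreq, 1)
  expect_equal(tr$realizedClass0AltFreq, 0)
})

test_that("realized signal frequencies sit in the binomial envelope", {
  spec <- syntheticSpec(list(
    geneSpec("g", 50L, nSignal = 1L, penetrance = 0.7, mLineages = 12L,
             leakage = 0.02)))
  ds <- generateDataset(spec, seed = 21)
  tr <- ds$truth@genes$g
  lin <- ds$truth@lineages
  sigLin <- strsplit(tr$signalLineages, ",")[[1]]
  nSig <- sum(lin$label == "C4" & lin$lineage %in% sigLin)
  altCount <- round(tr$realizedClass1AltFreq * 76)
  ci <- stats::qbinom(c(0.005, 0.995), nSig, 0.7)
  expect_gte(altCount, ci[1])
  expect_lte(altCount, ci[2])
  # class-0 leakage stays near its nominal rate
  expect_lte(tr$realizedClass0AltFreq,
             stats::qbinom(0.995, 58, 0.02) / 58)
})

test_that("unsignalled specs leave an empty truth and no association", {
  spec <- syntheticSpec(list(geneSpec("g", 80L)), nClass0 = 20L,
                        nClass1 = 24L, nLineages = 4L)
  ds <- generateDataset(spec, seed = 9)
  expect_equal(nrow(ds$truth@genes$g), 0L)
  rep <- verifyTruth(ds$alignments, ds$truth)
  expect_true(rep$ok)
  expect_equal(rep$nCheckedTruth, 0L)
  expect_gt(rep$nCheckedBackground, 0L)
})

test_that("verifyTruth passes fresh data and names corrupted columns", {
  ds <- generateDataset(smallSpec(), seed = 31)
  rep <- verifyTruth(ds$alignments, ds$truth)
  expect_true(rep$ok)
  expect_equal(rep$nCheckedTruth, 2L)
  # overwrite one truth column with noise
  bad <- ds
  ap <- ds$truth@genes$sig$ap[1]
  m <- as.matrix(bad$alignments$sig)
  m[, ap] <- "A"
  seqs <- setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
  bad$alignments$sig <- LabeledAlignment(
    seqs, "sig", labels = phenoLabels(ds$alignments$sig))
  expect_error(verifyTruth(bad$alignments, bad$truth),
               paste0("sig:", ap))
})

test_that("ambiguity sprinkling exercises the encoding contract", {
  spec <- smallSpec(ambiguityRate = 0.02)
  ds <- generateDataset(spec, seed = 41)
  m <- as.matrix(ds$alignments$noise)
  expect_true("X" %in% m)
  # encoding still round-trips with ambiguity letters present
  keys <- buildColumnKeys(ds$alignments$noise)
  fm <- encodeAlignment(ds$alignments$noise, keys)
  expect_identical(unname(decodeAlignment(fm, keys)),
                   unname(as.character(ds$alignments$noise@seqs)))
})

test_that("signal residues must differ between classes", {
  expect_error(geneSpec("g", 10L, nSignal = 1L,
                        signalResidues = list(c("A", "A"))),
               "identical")
})

test_that("label shuffling destroys planted signal", {
  spec <- syntheticSpec(list(
    geneSpec("sig", 50L, nSignal = 3L, penetrance = 0.95, mLineages = 6L,
             leakage = 0.01)),
    nClass0 = 24L, nClass1 = 28L, nLineages = 6L)
  ds <- generateDataset(spec, seed = 55)
  fm <- encodeAlignment(ds$alignments$sig)
  cfg <- cvConfig(nIterations = 40, masterSeed = 56)
  true <- quietCV(fm, config = cfg)
  null <- suppressWarnings(permutedLabelCV(fm, config = cfg))
  expect_gt(cvMeans(true)[["accuracy"]], 0.9)
  expect_lt(cvMeans(null)[["accuracy"]], 0.75)
})
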