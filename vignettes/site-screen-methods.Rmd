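---
title: "Methods: screening alignment sites for phenotype-classifying substitutions"
author: "siteScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening alignment sites for phenotype-classifying substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Convergent phenotypes — the motivating case is the repeated evolution of
C4 photosynthesis across PACMAD grass lineages — can leave repeated,
partially penetrant amino-acid substitutions in protein alignments.
`siteScreen` asks, for each protein alignment in a panel: *can the
columns of this alignment classify samples into the two phenotype
classes, and if so, which minimal set of columns carries that
information?*  The design constraint throughout is that the phenotype
arose independently in many lineages, so a classifier that succeeds must
be reading convergent, phenotype-linked states rather than shared
ancestry.

# The model and the three-stage screen

## Ordinal column encoding

Each alignment column becomes one integer feature.  A per-column key
maps every observed character (20 amino-acid letters, ambiguity letters,
and the gap `-`, all treated as ordinary states) to a code in
`0..N-1`, where `N` is the number of distinct characters in that
column.  Most alignment columns carry at most two states, so the
features are predominantly binary.  We assign codes by descending
character frequency, ties broken alphabetically; the assignment order is
arbitrary, and `permuteKeys()` exists precisely to demonstrate that the
screen's conclusions do not depend on it (for a binary column, swapping
the two codes is an affine transformation of the standardized feature
and leaves every fit's decision function unchanged up to a sign).
Ordinal coding of the rare `N > 2` columns places non-linearly related
states on one axis; this is a deliberate simplicity trade-off, and the
key-permutation robustness check is the guard against it mattering.

Keys are always built from the full alignment, never per
cross-validation split: the encoding uses no label information, so this
cannot leak class membership.

## Classifier and cross-validation (v1)

The base model is logistic regression with a ridge (L2) penalty of unit
strength (`lambda = 1`) on standardized features; the intercept is
unpenalized.  Ridge keeps coefficients finite even when a column
separates the classes perfectly, which matters because coefficient
magnitudes drive feature selection.  Performance is estimated by
repeated random subsampling: `nIterations` (default 500; the bundled
test configuration uses 50–100 to keep suite runtimes at desk scale)
independent random 70:30 train/test splits, a fresh standardization
*fit on the training portion only*, a fresh model fit, and accuracy,
AUROC, precision, recall and F1 computed on the untouched test portion.
Reported metrics are means over iterations.  The positive class for
AUROC/precision/recall is the lexicographically later label unless
configured otherwise.

Splits are simple random (unstratified).  A guard redraws any split
whose training *or* test portion lacks one of the classes — only the
training side strictly needs this for fitting, but a one-class test set
would make AUROC undefined; with the default 58/76 class sizes the
guard never triggers.

## Strongest features (v2)

A single fit on the entire dataset (standardization also on the full
dataset) yields signed coefficients of the decision function; the ten
largest by absolute value are the v2 feature set, re-evaluated by the
same CV procedure.  Magnitude ties resolve to the earlier alignment
position.

## Recursive feature elimination (v3)

Starting from the full-length alignment, each RFE step runs the complete
repeated-subsampling CV on the active columns, averages each column's
absolute standardized coefficient across the step's fits, and removes
the minimum — the "most consistent weakest" column (ties remove the
later position; an alternative criterion, the column most often ranked
weakest within single fits, is available behind
`criterion = "weakest-rank"`).  The recursion deliberately continues
past any accuracy plateau down to `minFeatures` (default 2), so the
performance of every subset size is known.  `optimalSubset()` then
returns, among steps with at most ten active features, the one with the
highest mean accuracy (ties: fewer features, then higher AUROC), and
flags whether it reaches the "optimal zone" of accuracy at least 0.9.

The same master-seed-derived splits are reused at every RFE step.  The
alternative — fresh splits per step — would only add between-step noise
to a comparison that is already averaged over many splits, and reusing
splits makes any step's summary exactly reproducible by an ordinary
`repeatedSubsampleCV()` call on that step's features.

## Complex models

For a multi-subunit complex, each subunit contributes its ten strongest
features (fewer for subunits shorter than ten columns); the selected
columns are concatenated in roster order and the full RFE-CV is rerun on
the combined matrix to an optimal cross-subunit set of at most ten
features.  The default roster covers NDH, ATP synthase, cytochrome b6f,
PSI, PSII (psbN excluded as likely not a supercomplex constituent) and
the two ribosomal subunit gene sets (rpl32 excluded, being absent from
several grass plastomes).

## Null models and comparisons

`permutedLabelCV()` repeats the identical CV procedure after replacing
the labels with one seeded permutation (class counts preserved); a gene
whose true-label metrics do not significantly exceed its permuted-label
metrics has no credible signal.  Distribution comparisons use the
classical equal-variance two-sample Student's t-test (Welch behind a
flag) with Bonferroni correction at a default family-wise alpha of
0.001.  `compareTopToPercentile()` implements the "better than 80% of
models" check: each gene ranked above the 80th percentile of v1 mean
accuracy is compared against the gene sitting at that percentile,
Bonferroni-corrected over the number of such comparisons — the most
direct reading of that summary statistic.

## Diversity statistics

Mean pairwise distance (MPD) is the average number of differing columns
over all unordered sequence pairs; a gap against a residue counts as a
difference, two gaps count as identical (counting shared gaps as
differences would inflate divergence for poorly overlapping rows; the
choice is recorded in output metadata).  It is computed per column from
character counts, which is algebraically the pairwise double loop.  MPD
per 100 residues normalizes by alignment length.  Correlations of
class-0-only MPD, length, and normalized MPD against per-gene optimal
accuracies use Pearson's r; class-0-only subsetting keeps variation
caused by the phenotype transitions themselves out of the diversity
measure.

# The synthetic data generator

`generateDataset()` emulates the structure of the real screen panel:
58 class-0 and 76 class-1 samples, class-1 partitioned into 16 lineage
blocks of as-even-as-possible size (independent phenotype origins),
per-gene alignments of 100–800 mostly two-state columns.  Background
columns are i.i.d. across samples and independent of labels: invariant
with probability 0.55, otherwise binary with a minor-state frequency
drawn uniformly from (0.02, 0.45), occasionally three-state (0.05) or
gapped (0.03).  Those rates were chosen once as representative of
plastid protein alignments (largely conserved, predominantly binary
variable sites, sparse gaps) and are user-configurable.  A planted
signal column gives class-0 samples a consensus residue apart from a
small leakage fraction, and gives class-1 samples in `m` chosen lineages
the alternative residue with penetrance `q` — lineage-restricted,
partially penetrant convergence.  Ground truth (positions, residues,
lineages, realized class-conditional frequencies) is recorded and
`verifyTruth()` re-derives it from the emitted alignments, additionally
chi-square-screening background columns for accidental label
association.

The default screen scenario (`defaultScreenSpec()`) has one strong gene
(475 columns, six planted sites, q = 0.9 across 13/16 lineages, 2%
leakage — strong but imperfect, like a best-case real gene), one
moderate gene (q = 0.6, 8/16 lineages), and eight null genes spanning
100–800 columns.

What the generator does *not* emulate: phylogenetic covariance among
background columns (no tree simulation — the pipeline never uses a tree,
and lineage structure matters only for where signal sits), substitution
models, alignment error, or length variation from indel evolution.
Passing tests on synthetic data therefore demonstrate the machinery —
encoding, leakage-free CV, elimination, null calibration — not that any
particular real alignment carries signal.

# Numerical choices

* **Solver.** Fits run in the dual (sample) space on the Gram matrix of
  standardized training features (columns far outnumber samples), with
  IRLS/Newton steps, step-halving on the penalized deviance, and a
  convergence tolerance of 1e-9 on the linear predictor.  The intercept
  is a pseudo-feature of scale 100, making its effective penalty 1e-4 of
  a feature's — numerically indistinguishable from unpenalized (the test
  suite cross-checks coefficients against an independent ridge-logistic
  implementation at much tighter agreement than this bias).  During RFE
  the per-split Gram matrices are downdated by a rank-1 term per
  elimination, so a full path costs little more per step than one CV
  run.
* **Standardization** uses the population (divide-by-n) standard
  deviation; columns constant in a training split get scale 1 and,
  exactly, weight 0.
* **Seeding.** Iteration `i` uses seed `masterSeed + i`, so any single
  iteration is reproducible in isolation; key permutation, label
  permutation and data generation consume their own seeds.  Identical
  inputs give byte-identical reports.
* **Degenerate inputs.** Single-class labels, sub-2-column alignments,
  unlabeled samples and unknown feature ids fail fast with specific
  errors; genes shorter than `minFeatures` are reported with v1 metrics
  only and flagged.
* **Tie-breaks** are all deterministic and stated: code assignment
  (frequency, then alphabet), elimination (later position), selection
  (earlier position), optimum (accuracy, then fewer features, then
  AUROC).

# Known limitations

* Greedy elimination is not exhaustive search: on small noisy instances
  the exhaustive best pair *as estimated by CV* can exceed the RFE
  optimum by a winner's-curse margin even when RFE retained the truly
  informative columns; the oracle-equivalence check therefore uses an
  instance with graded feature strengths where the best subset is
  well-determined.
* With partial penetrance, the accuracy-optimal subset may include a few
  background columns that happen to tag unsignalled lineages;
  recovered-position counts should always be read against ground truth
  (synthetic) or structural/biochemical context (real data).
* Encoding invariance is exact for binary columns (a code swap negates
  the standardized feature, which changes nothing), and planted
  positions are recovered identically under arbitrary re-keying.  But
  when the optimum contains chance-correlated background columns, a
  *full* shuffle of multi-state column codes can change which of those
  weak companions survive elimination: the identity of noise columns in
  an optimal set is not an encoding-invariant quantity, and should never
  be interpreted.
* Ordinal coding of multi-state columns, and the absence of interaction
  terms, mean the screen detects per-column convergent states, not
  epistatic combinations.
* The per-gene screen is marginal: correlated genes (linked sites,
  shared lineage structure) are screened independently, and complex
  models inherit whatever correlation their subunits share.
* The permutation null uses one label permutation per gene and compares
  metric distributions across CV iterations.  Iterations share the same
  dataset and permutation, so the t-test's independence assumption is
  optimistic: on a signal-free gene the true-versus-permuted difference
  is dominated by the single dataset/permutation draw, and an occasional
  small-but-"significant" flag in either direction is expected noise.
  Strong conclusions should rest on the size of the gap (as for genuine
  signal genes, where accuracy gaps are tens of points), not on the
  p-value alone.

# A worked miniature

```{r}
library(siteScreen)
spec <- syntheticSpec(list(
  geneSpec("sig", 60, nSignal = 2, penetrance = 0.95, mLineages = 14,
           leakage = 0.02),
  geneSpec("noise", 80)))
ds <- generateDataset(spec, seed = 1)
cfg <- cvConfig(nIterations = 50, masterSeed = 1)
rep <- screenGenes(ds$alignments, cfg)
rep@table[, c("gene", "v1_accuracy", "v3_features", "v3_accuracy")]
ds$truth@genes$sig$ap   # compare with the recovered v3 positions
```
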