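Package: siteScreen
Title: Machine-Learning Screen for Phenotype-Informative Alignment Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein alignments, and residue positions within
    them, that carry information distinguishing two phenotype classes
    (for example C3 versus C4 photosynthetic type in grass plastomes).
    Alignment columns are ordinally encoded with per-column character
    keys, ridge-penalized logistic classifiers are evaluated by repeated
    random-subsampling cross-validation, informative positions are
    extracted by a recursive feature elimination that continues past
    accuracy plateaus to minimal feature sets, subunit models are
    combined into multi-protein complex models, permutation-label null
    models calibrate significance, and mean pairwise distance statistics
    relate alignment diversity to classifier accuracy. A synthetic-data
    generator plants lineage-restricted, partially penetrant convergent
    substitutions so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    seqinr,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
biocViews: Classification, MultipleSequenceAlignment, FeatureExtraction,
    Phylogenetics, SupportVectorMachine
RoxygenNote: 7.3.3
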