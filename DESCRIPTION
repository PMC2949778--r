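Package: twistmap
Title: Evolutionary Feature Selection, Neural Classification and Semantic
    Connectivity Mapping for Folate-Pathway Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating mothers of Down-syndrome children from
    control mothers using folate-pathway polymorphisms and the lymphocyte
    micronucleus frequency. Implements one-hot genotype coding of biallelic
    loci, a genetic-algorithm wrapper (random-immigrant "doping", tournament
    selection) that jointly optimizes an input-variable mask and a
    train/test split scored by two-direction generalization accuracy of an
    inner multilayer perceptron, a 5x2 cross-validation protocol reporting
    sensitivity, specificity, global accuracy and ROC AUC, and an
    Auto-Contractive Map whose trained pairwise weights are filtered through
    a minimum spanning tree into a semantic connectivity graph. A calibrated
    synthetic-cohort generator with plantable linkage-disequilibrium
    couplings and noise loci makes every stage testable without subject
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
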