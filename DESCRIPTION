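Package: lysoprofiler
Title: Lysosomotropism Scoring, Matched Molecular Pairs and Explainable
    Classification from Morphological Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores compound-induced lysosomotropism from cell painting
    morphological profiles (Z-scored feature vectors, induction, Pearson
    biosimilarity to a reference phenotype), filters compound libraries to
    the physicochemical window where lysosomotropism is plausible (log P and
    basic pKa), performs matched-molecular-pair analysis of the lyso score,
    trains class-weighted gradient-boosted tree classifiers on molecular
    descriptors or Morgan fingerprints, and explains them with exact
    path-dependent tree Shapley values including a fingerprint-bit to
    substructure report. Ships a synthetic-data generator that emulates the
    structure of such screening data so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    xgboost,
    data.table,
    caret,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
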