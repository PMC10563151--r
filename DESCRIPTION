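Package: csnn
Title: Weakly Supervised Cell-Level Scoring of Flow Cytometry Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns per-cell pathogenicity scores from flow cytometry
    cohorts that carry only sample-level annotation (a binary diagnosis
    and, optionally, a cancer burden in [0,1]). A small feedforward
    scoring network maps each cell's marker vector to a probability, the
    per-sample mean of the scores is the sample-level prediction, and the
    network is trained end-to-end against the sample labels (regression on
    burden or logistic classification on diagnosis). Training can be
    initialized from a kernel-density Bayes-rule estimate of the cell
    scores. Identified cells are interpreted with post-hoc decision trees
    over the marker panel and validated with a cancer-only cluster check.
    Includes FCS and tabular event readers, a synthetic cohort generator
    with cell-level ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    rpart,
    pROC,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
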