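Package: donorNet
Title: Network-Based Donor Kidney Molecular Models and Post-Transplant
    Renal Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing network-based molecular models of renal
    donor organ status and for predicting twelve-month post-transplant
    estimated glomerular filtration rate (eGFR). Gene feature sets from
    several evidence sources are merged into a catalog, projected onto a
    protein-interaction network, clustered into densely interconnected
    molecular processes with the MCODE algorithm, and tested for Gene
    Ontology term overrepresentation. Marker expression (quantile
    normalization, probe-to-gene summarization, outlier screening) is
    combined with clinical covariates in linear models selected by
    simulated annealing minimizing leave-one-out cross-validated RMSE,
    with nested-model ANOVA comparisons against clinical-only baselines.
    A synthetic-data module generates planted-truth networks, annotations
    and transplant cohorts for validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    limma,
    jsonlite,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
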