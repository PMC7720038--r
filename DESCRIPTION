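Package: pardsub
Title: Transcriptomic Sub-Phenotype Discovery and Outcome Modeling for
    Pediatric ARDS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-blood transcriptomic sub-phenotyping of pediatric acute
    respiratory distress syndrome (ARDS) cohorts: k-means subtype discovery
    with gap-statistic selection of the number of clusters under a
    minimum-cluster-size rule, subtype characterization against clinical
    variables (Freeman-Halton Fisher exact tests, Kruskal-Wallis tests with
    rank-based eta-squared effect sizes), subtype-outcome inference (logistic
    regression for PICU mortality; Fine-Gray subdistribution-hazard regression
    for extubation with death as a competing risk; Kaplan-Meier and log-rank),
    one-vs-rest differential expression with fold-change and FDR gates, and a
    synthetic cohort generator with planted expression subtypes,
    subtype-linked covariates, and competing-risk outcomes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cmprsk,
    limma,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
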