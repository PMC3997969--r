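Package: hetrank
Title: Ranking Cancer Genes by Interindividual Expression Variation in Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing cancer-associated genes from two-group
    (adjacent normal vs tumor) expression matrices using six per-gene
    predictors: group means m(AN) and m(T), group standard deviations SD(AN)
    and SD(T), fold change, and -log10 p from a pooled two-sample t test.
    Implements Mann-Whitney comparison of predictors between labeled cancer
    genes and all other genes, top-5% enrichment-factor ranking, 4-SD outlier
    calling in tumors with -log10(p)-matched control genes, a simulation
    study contrasting a shifting-means model of tumor expression with an
    outliers (tumor-heterogeneity) model, stepwise-forward likelihood-ratio
    logistic combination of the predictors, and synthetic cohort generators
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
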