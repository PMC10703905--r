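Package: transomix
Title: Trans-Omic Rank Aggregation of Multi-Omics Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates genome-wide association, DNA-methylation, and gene-
    expression studies of coronary outcomes into per-gene trans-omic scores.
    Implements a three-stage pipeline: per-feature association testing with
    cluster-robust (sandwich) variance for family-structured cohorts, gene-
    level min-p collapsing, and robust rank aggregation of truncated top-
    fraction gene lists via order-statistic beta scores. Ships a synthetic
    multi-omics cohort generator with planted effects so the full pipeline is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
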