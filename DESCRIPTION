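Package: mimisurv
Title: Survival Analysis of miRNA-mRNA Integration Sets via Penalized
    Structured-Component Cox Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links miRNA-mRNA integration sets to survival time with a
    hierarchical structured-component Cox proportional-hazards model
    fitted by alternating block ascent on a doubly penalized partial
    likelihood (ridge, lasso, or Elastic-Net penalties on both the
    within-set weights and the set-level effects). Includes the negative-
    correlation pair-filtering front end for microarray and zero-inflated
    sequencing data, permutation and maxT significance testing with
    Benjamini-Hochberg q-values, miRNA-only penalized Cox baselines,
    and a simulation engine for type-I error and power studies with
    controlled censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
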