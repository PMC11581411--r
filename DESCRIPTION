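Package: mvmrset
Title: Multivariable Mendelian Randomization with Correlated Instrumental Variable Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and estimation of direct causal effects of multiple
    exposures (typically cis-regulated gene expression traits) on an outcome using
    sets of correlated genetic instruments. Implements the instrumental-set
    identification criterion for linear structural equation models via Wright's
    method of path coefficients and d-separation, least-squares and generalized
    method of moments (two-stage least squares) estimators from summary
    covariances, instrument-strength and determinacy diagnostics (conditional
    F-statistics, rank and determinant checks), a scenario simulator with
    linkage-disequilibrium-aware binomial genotypes, and a locus-construction
    pipeline that builds closed causal diagrams at GWAS loci from eQTL and GWAS
    summary statistics to predict causal genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
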