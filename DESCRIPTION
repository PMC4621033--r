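Package: metagsa
Title: Concordance-Weighted Meta-Analysis of Gene-Set Analyses Across
    Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines gene-set-analysis (GSA) p-values from several
    genome-wide association studies with a weighted Fisher inverse
    chi-square statistic, weighting each study by the concordance of its
    gene-level association pattern. Gene-level evidence is summarised as
    directed reversed p-values (PDRs), between-study concordance is
    measured with Kendall's tau, study weights are derived from the first
    principal component of the concordance matrix, and significance is
    assessed by a permutation procedure with a pi0-based correction for
    multiple testing. Also provides the comparator methods (simple
    p-pooling, pooled-GWAS GSA via per-marker random-effects
    meta-analysis, one-sided Wilcoxon rank-sum GSA) and a case-control
    GWAS simulator for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse
Config/testthat/edition: 3
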