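Package: candigene
Title: Candidate-Gene Case-Control Association Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete candidate-gene case-control association workflow for
    small tag-SNP panels: per-SNP quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test), single-marker association under
    additive, dominant and recessive codings with covariate-adjusted logistic
    regression and an allele-count test, confidence-interval based D-prime
    linkage-disequilibrium blocks (Gabriel rule), EM haplotype frequency
    estimation with per-haplotype and omnibus tests, exhaustive
    cross-chromosome two-locus epistasis scanning with max-statistic
    permutation family-wise correction, fixed- and random-effects odds-ratio
    meta-analysis, and case-control genetic power calculation. Includes a
    synthetic cohort generator that emulates a tag-SNP study design so every
    stage is testable without external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    metafor,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
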