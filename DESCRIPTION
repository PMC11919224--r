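Package: famprs
Title: Familial Versus Population Polygenic Risk Score Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a weighted polygenic risk score (wPRS) for a complex
    disease from GWAS summary statistics, scores genotyped case-control
    cohorts and multicase pedigrees, and compares familial cases and their
    unaffected relatives against population cases and controls. Provides
    summary-statistic harmonization (ambiguous-SNP exclusion, strand and
    allele orientation), Welch two-sample tests, ROC/AUC discrimination with
    DeLong confidence intervals, an iterative cohort-subsampling comparison,
    a pedigree-kinship-aware linear mixed model with rank-based inverse
    normal transformation, and a liability-threshold simulator of cohorts
    and multicase families for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
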