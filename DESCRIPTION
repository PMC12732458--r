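Package: prsphewas
Title: Polygenic Risk Scores and Phenome-Wide Association Scans for
    Biobank Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genotype-array case-control studies of
    complex disease: an eleven-step sample- and variant-level quality-control
    cascade (sex concordance, call rates, method-of-moments inbreeding and
    identity-by-descent relatedness, exact Hardy-Weinberg testing in controls,
    differential missingness, strand flipping), covariate-adjusted logistic
    genome-wide association with genomic-inflation diagnostics and
    linkage-disequilibrium clumping, rare-variant qualifying-variant selection
    and gene-level carrier-burden collapsing, clumping-and-thresholding
    polygenic risk scores under multiple SNP-set restrictions with summary
    statistic allele harmonization, cross-validated risk-stratification
    evaluation with quintile odds ratios, and variant-level and score-based
    phenome-wide association scans over ICD-10 codes and phecodes. A
    liability-threshold cohort simulator with block-structured linkage
    disequilibrium, planted causal variants, a synthetic electronic-health-record
    phenome and injectable quality-control defects makes every stage testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    pROC
Config/testthat/edition: 3
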