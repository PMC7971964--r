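Package: mrtriangulate
Title: Triangulating Adjusted Multivariable Regression and Two-Sample
    Mendelian Randomization for Metabolomic Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for combining observational and genetic
    evidence on the effects of sleep traits (insomnia symptoms, sleep
    duration, chronotype) on NMR-metabolomic outcomes. Provides GWAS
    summary-statistics input/output and validation, genetic instrument
    selection (genome-wide significance filtering, palindromic-SNP
    exclusion, greedy LD clumping, risk-allele reorientation,
    F-statistics), exposure/outcome allele harmonization, two-sample
    Mendelian randomization estimators (Wald ratio, multiplicative
    random-effects IVW, MR-Egger, weighted median with parametric
    bootstrap), fixed-effect and DerSimonian-Laird random-effects
    meta-analysis, per-cohort age-, sex-, and BMI-adjusted regression of
    metabolites on exposures, and a triangulation layer that applies a
    Bonferroni threshold based on the effective number of independent
    metabolomic dimensions and classifies cross-method consistency. A
    seeded synthetic-data generator emulates the two-sample design
    (liability-model binary exposures, latent-factor metabolite panels,
    block LD, pleiotropy, confounding) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
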