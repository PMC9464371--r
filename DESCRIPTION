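Package: pleioscan
Title: Multi-Trait Pleiotropy Scanning with Adaptive Powered-Score Tests and
    Causal Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and dissecting genetic
    pleiotropy between inflammation (C-reactive protein) and adiposity traits
    (body-mass index and sex-stratified waist-to-hip ratio) from GWAS summary
    statistics. Provides phenotype preparation (log transform, outlier
    exclusion, covariate residualization, inverse-normal transform),
    univariate association testing with cluster-robust sandwich variance,
    fixed-effect inverse-variance meta-analysis, the adaptive Sum of Powered
    Score (aSPU) multi-trait test with staged Monte-Carlo p-values, LD
    clumping with candidate and replication decision rules, and a
    quasi-Bayesian linear causal-mediation decomposition (ACME/ADE) with
    sequential-ignorability sensitivity analysis. A synthetic-cohort
    generator with known pleiotropic, mediated, single-trait and null
    variants makes every stage testable without access to individual-level
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
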