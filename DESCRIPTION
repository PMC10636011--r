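Package: fallmr
Title: Phenotyping, Heritability and Mendelian Randomisation for
    EHR-Derived Fall Susceptibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for studying the causes of
    balance-related falls from coded electronic health records and
    genome-wide association summary statistics. Derives case/control fall
    phenotypes and per-person fall counts from ICD-10 and Read-coded event
    logs, runs variant quality control and Firth-penalised logistic
    association scans, estimates SNP heritability and cross-trait genetic
    correlation by LD score regression with block-jackknife uncertainty,
    and provides a full Mendelian randomisation suite: one-sample
    two-stage estimation with linear, logistic or Poisson second stages,
    two-sample inverse-variance-weighted, MR-Egger, weighted-median and
    penalised-weighted-median estimators, sex-stratified and
    negative-control analyses, and an overlap-, weak-instrument- and
    winner's-curse-corrected IVW with an observed-versus-corrected
    difference test. A seeded synthetic-data generator with known ground
    truth makes every stage testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
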