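Package: colliderbias
Title: Collider Bias Correction for Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumental-variable correction of collider bias in
    genome-wide association studies that condition or stratify on a
    heritable covariate. Estimates the bias slope from two sets of GWAS
    summary statistics by corrected weighted least squares (CWLS), a
    weighted errors-in-variables regression that undoes weak-instrument
    attenuation, alongside the uncorrected inverse-variance-weighted
    estimator and a two-component bivariate-normal mixture estimator.
    Adjusts per-SNP conditional or total effects toward direct effects
    with delta-method standard errors, provides a Heckman two-step
    correction for individual-level selected samples, and includes a
    summary-statistic and individual-level simulator with experiment
    drivers for Type-1 error, power, slope recovery and sign-change
    studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
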