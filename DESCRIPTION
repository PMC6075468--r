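Package: lcsem
Title: Bivariate Latent Change Score Structural Equation Models for
    Longitudinal Biomarker-Neuroimaging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying coupled change between a blood biomarker and
    brain MRI measures across two measurement waves. Implements a general
    path-model (RAM) engine with casewise full-information maximum likelihood
    for missing data, equality constraints, observed-information standard
    errors, standardized solutions, chi-square/RMSEA/CFI/TLI/SRMR fit indices,
    and bias-corrected bootstrap confidence intervals; builders for univariate
    and bivariate latent change score models, latent white-matter factors
    under strong factorial invariance, covariate correction, and
    auxiliary-variable augmentation; preprocessing rules (exclusions, assay
    floor and outlier filters, log and intracranial-volume transforms); a
    calibrated synthetic two-wave cohort generator with missing-at-random
    attrition; and a reporting pipeline with Benjamini-Hochberg false
    discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
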