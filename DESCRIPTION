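Package: odontomech
Title: Mechanical Stability Analysis for Odontoid Fracture Fixation Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for destructive compression tests of odontoid
    (dens) fracture fixations. Extracts stiffness, yield load and ultimate
    load from load-displacement curves using a moving-kernel maximum-Pearson
    linear regression and a correlation-decay yield criterion; normalises
    paired intact/instrumented outcomes into percentages of stability
    restored; computes the cortical-to-total cross-sectional area ratio from
    polyline contours; and runs the covariate-adjusted group comparison
    (homogeneity-of-slopes check, one-way ANCOVA with adjusted means, linear
    regressions, Mann-Whitney U tests). Includes a synthetic-data generator
    producing load-displacement curves with known ground truth and paired
    two-group cohorts for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    jsonlite
Config/testthat/edition: 3
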