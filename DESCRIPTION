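Package: diurnalAab
Title: Diurnal Variation Analysis of Islet Autoantibody Titers
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying diurnal variation in islet autoantibody
    (GADA, IA, IA-2A, ZnT8A) and immunoglobulin titers in type 1 diabetes.
    Implements single-component 24-hour cosinor rhythmometry on participant
    z-scored longitudinal panels, nested variance-components decomposition of
    titer variation (between-participant, time-of-day, intra-assay), bootstrap
    comparison of time-restricted versus random-time sampling precision, and a
    cross-sectional pipeline that discovers age-by-sampling-time subgroups with
    a regression tree and compares their mean log titers (ANOVA, fold changes)
    and detection rates (exact binomial intervals, chi-square). A synthetic
    data generator reproduces the statistical structure of both study designs
    so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
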