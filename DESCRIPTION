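Package: gaitrel
Title: Gait Events, Spatiotemporal Parameters, and Between-Session
    Reliability of Lower-Limb Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for test-retest gait analysis from bilateral joint-angle
    and landmark time series: coordinate-based detection of initial contact
    and toe-off, stride segmentation and time normalization to the gait
    cycle, extraction of discrete kinematic variables and spatiotemporal
    parameters, and absolute-reliability statistics (full-curve RMSD,
    standard error of measurement via repeated-measures ANOVA, SEM%).
    Includes a synthetic two-session gait-cohort generator with known
    variance components for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
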