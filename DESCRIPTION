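Package: anaerocap
Title: Anaerobic Capacity Estimation for Treadmill Running Time Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates anaerobic capacity during maximal treadmill running
    time trials from indirect calorimetry, using maximal-accumulated-oxygen-
    deficit (MAOD) style speed-metabolic-rate regression models and fixed
    gross-energy-cost models. Converts gas exchange to metabolic rate with a
    Weir-type equation, fits linear, quadratic, reduced-stage and fixed-cost
    demand models to submaximal stages, decomposes the time-trial energy
    requirement into aerobic and anaerobic rates at 1 Hz, and quantifies
    between-model agreement with Bland-Altman limits of agreement, typical
    error, Hedges g_av, repeated-measures ANOVA with Greenhouse-Geisser
    correction, and ICC-based standard error of measurement. Includes a
    synthetic-participant generator with known ground-truth anaerobic
    capacity for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
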