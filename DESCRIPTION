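Package: tiadose
Title: Time-Activity Curve Fitting and Absorbed-Dose Variability for
    Radiopharmaceutical Therapy Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for organ- and lesion-level internal dosimetry in
    radiopharmaceutical therapy.  Provides mono- and biexponential
    time-activity models with closed-form time-integrated activity (TIA)
    integrals, Levenberg-Marquardt curve fitting with optional physical
    decay-rate constraints and weighting, a catalog of piecewise TIA
    assembly methods (head/body/tail rules over three integration
    intervals, including trapezoidal interpolation and tail
    extrapolation), organ-level dose-factor conversion with mass-weighted
    kidney combination and decay-correction handling, robust variability
    statistics (quartile coefficient of dispersion, interquartile-range
    outlier fences, paired task comparisons), and a seeded synthetic
    multi-participant cohort generator with injectable analysis-error
    modes for virtual multi-center variability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
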