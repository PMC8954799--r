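Package: phytodoe
Title: Full-Factorial Design and Response-Surface Modelling of Plant
    Trace-Metal Bioindication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating the trace-metal bioindication ability of a
    plant species with a full-factorial design of experiment. Generates
    replicated factorial designs over coded nutrient-solution concentrations,
    fits the ten-term quadratic response-surface model (linear, binary
    interaction and squared effects) for each shoot-metal response by ordinary
    least squares, evaluates response and 95% confidence-semiamplitude
    surfaces over any pair of coded factors, and classifies each metal as
    bioindicator or not from the pattern of significant coefficients. Includes
    the atomic-absorption quantification chain (calibration lines, blank
    subtraction, limit of detection, dilution, spike-recovery and
    control-solution checks) and a synthetic-data generator that emulates a
    hydroponic uptake study on Polygonum aviculare, so the whole pipeline can
    be exercised and benchmarked without access to the raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
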