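Package: msaif
Title: Non-Radiometric Arterial Input Functions for Carbon-11 PET Tracers by
    LC-MS/MS Carrier Quantification
Version: 0.1.0
Authors@R:
    person("Analytical", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for determining the arterial input function (AIF) of a
    carbon-11 labeled PET radiotracer without measuring radioactivity.
    Implements isotopologue-based molar-activity (Am) measurement from
    LC-MS/MS peak areas, internal-standard calibration and quantification of
    tracer carrier in plasma with correction for the cyclotron-induced
    13C/12C isotope skew, conversion between carrier amount and
    radioactivity via Am and the carbon-11 decay constant, construction of
    AIFs in radioactivity units, estimation of the systematic gamma-counter
    bias, and method-comparison statistics (trapezoidal AUC, test-retest
    variability, Pearson correlation, absolute-agreement intraclass
    correlation, paired t test). A synthetic-study generator with full
    ground truth emulates cyclotron 11C/13C co-production, carrier
    contamination, multi-exponential plasma clearance, declining parent
    fraction, and detector bias, so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
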