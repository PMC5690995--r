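Package: compcomm
Title: Commissioning Compensator-Based IMRT Beam Models with Chi-Squared
    and Gamma-Index Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for commissioning a treatment-planning-system surrogate
    model of brass compensator transmission for intensity-modulated
    radiotherapy (IMRT). Implements a two-parameter compensator model
    (brass density and a modified scatter factor), chi-squared parameter
    sweeps against slab-attenuation measurements with a
    minimum-of-minima density search, a from-scratch two-dimensional
    gamma-index comparison of measured and calculated dose planes with
    failing-point counting, and a synthetic-data generator producing
    noisy slab measurements and seven-field compensator-modulated dose
    planes sampled on a diode array, so the whole commissioning pipeline
    can be exercised end to end with parameter recovery as the check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
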