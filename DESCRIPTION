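Package: ftirclean
Title: FTIR-Based Pharmaceutical Cleaning Verification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning and evaluating rapid pharmaceutical
    cleaning verification with a hand-held mid-infrared (FTIR)
    spectrometer. Simulates residue-bearing stainless-steel coupons and
    their specular-reflectance spectra, fits a partial least squares
    (NIPALS) calibration mapping spectra to surface residue (ug/cm2),
    estimates the number of measurement points required per
    hard-to-clean location via a Student-t margin of error and the CpK
    method-capability index, derives limits of detection and
    quantification from fixed-point replicate measurements, and issues
    pass/fail verification verdicts gated on visual inspection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
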