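Package: hba1cspec
Title: Molar Absorption Spectra of Glycated Hemoglobin from Optical
    Transmittance Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving the molar absorption coefficient spectrum
    of glycated hemoglobin (HbA1c) from UV-Vis transmittance or absorbance
    measurements. Implements Beer-Lambert transmittance/absorbance
    conversions, a reference-anchored scaling method that converts a
    relative absorbance spectrum to absolute molar absorption units using
    literature anchor values, a concentration-series regression method
    that isolates the HbA1c component from a glycated/non-glycated
    hemoglobin mixture via the glycated molar fraction, Q-band peak
    detection, a three-zone Clarke-style error-grid analysis on the NGSP
    HbA1c scale, and a synthetic spectrum generator (Gaussian band models,
    Beer-Lambert mixing, replicate noise) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
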