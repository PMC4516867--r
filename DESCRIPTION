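Package: denaquant
Title: Isotope-Dilution LC-MS Quantification of Denatonium with a
    Deuterated Internal Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying denatonium (Bitrex) by isotope-dilution
    liquid chromatography mass spectrometry using an alpha-C-dideuterated
    internal standard prepared by base-catalysed hydrogen-deuterium
    exchange. Provides theoretical isotopologue envelopes from molecular
    formulas, a kinetic model of the labeling and back-exchange chemistry,
    non-negative least-squares deconvolution of overlapping light/heavy
    isotopic envelopes into mixture fractions, extracted-ion-chromatogram
    peak detection with co-elution and peak-purity diagnostics, calibration
    fitting with limit-of-detection estimation, and a seeded generator of
    synthetic centroid LC-MS runs for validating the whole chain.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
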