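Package: ftirtox
Title: FTIR Metabolome-Based Ecotoxicological Bioassay for Lignocellulosic Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a yeast (Saccharomyces cerevisiae)
    biosensor bioassay that reads inhibitor stress from Fourier-transform
    infrared (FTIR) absorbance spectra. Implements spectral preprocessing
    (quality test, rubberband baseline correction, vector normalization),
    window-wise spectral stress indexes computed as length-normalized
    Euclidean distances against unstressed controls, cell mortality from
    viable counts, quadratic inverse-calibration models that predict the
    relative concentration of lignocellulosic inhibitors (acetic acid,
    formic acid, furfural, HMF) from stress indexes, weighted general
    models combining spectral regions, quartile classification of
    predicted concentrations, and model evaluation. A synthetic-data
    generator emulates complete bioassay experiments so that every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
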