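Package: mushspec
Title: Visible-Range Reflectance Chemometrics for Mushroom Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Chemometric analysis of visible-range (450-760 nm) diffuse
    reflectance spectra for non-destructive quality assessment of white
    button mushrooms (Agaricus bisporus). Implements inter-instrument
    offset calibration, spectral preprocessing (Savitzky-Golay smoothing,
    min-max normalization, standard normal variate, multiplicative scatter
    correction), characteristic-wavelength selection by the successive
    projections algorithm, principal component reduction, moisture-content
    prediction by partial least squares regression and by a
    Levenberg-Marquardt-trained feedforward network whose initial weights
    can be optimized with the sparrow search algorithm, and CIE 1964
    tristimulus / Ganz whiteness computation with four-level browning
    grading. A synthetic-spectra generator with known ground truth supports
    development and validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
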