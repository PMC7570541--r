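Package: lactospec
Title: Quantitative Optical Spectroscopy of Lactate in Buffered Saline
Version: 1.0.0
Authors@R:
    person(given = "Package", family = "Author",
           role = c("aut", "cre"), email = "author@example.com")
Description: Simulation and multivariate calibration of sodium lactate
    concentration from UV/visible, near-infrared and mid-infrared absorbance
    spectra of buffered saline samples. Provides a SummarizedExperiment-based
    container for spectra sets, a Beer-Lambert synthetic-spectra generator
    built from published water and lactate band assignments (including the
    water-displacement confound of equivolume dilution), a preprocessing chain
    (noise-region masking, base-spectrum subtraction, robust linear
    multiplicative scatter correction, Savitzky-Golay derivative filtering),
    and from-scratch NIPALS PLS1 regression with PRESS-based latent-variable
    selection and leave-one-out cross-validation reporting (R2, RMSECV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pracma,
    signal,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
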