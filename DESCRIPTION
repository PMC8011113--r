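Package: lwcspectra
Title: Hyperspectral Estimation of Winter Wheat Leaf Water Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometric pipeline for estimating winter wheat leaf water
    content (LWC, percent of fresh mass) from 350-2500 nm canopy reflectance
    spectra. Provides atmospheric band masking, first-derivative spectra,
    exhaustive two-band vegetation-index optimization (normalized, ratio and
    difference forms) with R-squared contour maps, a catalogue of literature
    water indices, two characteristic-band screening methods
    (correlation-extremum selection and PLS x-loading-weight extrema), four
    regression models (PLSR, random forest, extremely randomized trees,
    k-nearest neighbours), and model evaluation by R-squared, RMSE and the
    ratio of performance to deviation (RPD). A synthetic canopy-reflectance
    generator emulating a two-year irrigation-treatment field design supplies
    reproducible data with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    ranger,
    caret,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
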