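Package: ramanev
Title: Quantification of Deuterium-Labelled Extracellular Vesicle Uptake in
    Raman Hyperspectral Cell Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to image and quantify deuterium-labelled extracellular
    vesicles (EVs) in confocal Raman hyperspectral images of cells. Implements
    the spectral preprocessing chain (cropping, morphological 'shape' baseline
    removal, area-under-curve normalisation, exterior-spectrum system
    background subtraction), univariate band-window imaging of subcellular
    components, a full-width-at-half-maximum deuterium metric for the
    silent-region C-D band, single-EV trapping-spectrum C-D/C-H peak ratios,
    automated inside/outside uptake quantification with signed
    distance-to-membrane statistics, and principal component analysis of
    deuterium-positive pixel spectra. A synthetic-data module generates
    hyperspectral cell phantoms and trapping spectra with known ground truth
    so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    rhdf5,
    withr,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
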