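Package: seagrassRS
Title: Seagrass Extent, Leaf Area and Blue Carbon from Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-automated analysis pipeline for monitoring subtidal
    seagrass from multispectral satellite-like imagery. Provides a synthetic
    scene generator with a physically motivated water-column forward model,
    dark-object-subtraction atmospheric correction, a five-class per-pixel
    neural classifier with exact Shapley band attribution, retrieval of
    bottom reflectance and leaf area index (LAI) through the water column,
    conversion of LAI to fresh/dry biomass and belowground organic carbon,
    seasonal Mann-Kendall and Theil-Sen trend statistics with a trend
    detectability (gamma) measure, per-pixel seagrass frequency maps,
    climate-driver multiple regression, and map-agreement assessment
    (precision/recall/F, overall accuracy, Cohen's kappa, McNemar).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nnet,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
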