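Package: lakeTSI
Title: Lake Trophic State Retrieval from Multispectral Surface Reflectance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel retrieval of the Carlson trophic state index (TSI) for
    inland lakes from Landsat-style surface-reflectance scenes. Implements the
    spectral indices used to separate optical water types (NDWI, FAI, TWI and
    the algal biomass index ABI), a decision-tree classifier for
    algae-dominated, turbid and clear water pixels, per-type linear ABI-to-TSI
    inversion, per-lake annual aggregation with Mann-Kendall/Sen trend tests,
    matchup-based model calibration and validation metrics, and a synthetic
    scene generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
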