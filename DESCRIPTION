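Package: earlyvigor
Title: Early Plant Vigor Assessment from RGB Imaging and Hyperspectral Canopy Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing early plant vigor of cereal stands from
    proximal sensing. Segments green canopy from soil in nadir RGB quadrat
    images in HSV color space to obtain canopy cover, computes narrow-band
    hyperspectral vegetation indices (NDVI, NDRE, REIP, ATSAVI and others)
    and an emulated two-band active-sensor NDVI, estimates fractional
    vegetation cover by two-endmember linear spectral unmixing, screens all
    pairwise normalized-difference band combinations against reference
    traits in contour-map matrices, and aggregates correlation level and
    temporal stability (mean and CV of R-squared) into a summary table.
    Includes a synthetic field-trial generator (spectra, rendered canopy
    images and trait tables with known ground truth) for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
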