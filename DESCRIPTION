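Package: larvaSeg
Title: 3D Segmentation and Quantification of Fluorescent Cells in
    Zebrafish Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless processing of multi-channel 3D confocal stacks of
    zebrafish larvae xenografted with fluorescently labelled cancer cells.
    Flattens stacks (max projection for fluorescence, sharpness-based focus
    stacking for brightfield), realigns larvae to a standardised pose from a
    user-supplied outline polygon (Feret-angle orientation, distance-map
    yolk-sac anchor), segments cells with a seeded 3D watershed (3D median
    pre-filter, local-maximum seeding above a background cutoff), measures
    per-object volume, equivalent spherical diameter, centroid and channel
    intensities, gates viable cells by volume, summarises per-larva tumour
    burden with Welch's t-test group comparison, pools cell coordinates into
    normalised kernel density maps, and estimates heart rate from
    intensity-trace videos by FFT. Includes a deterministic synthetic-data
    generator with ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    png,
    jsonlite,
    xml2,
    mgcv,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
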