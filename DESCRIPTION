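Package: speckleflow
Title: Laser Speckle Flowmetry, Neurovascular Coupling, and Vessel
    Morphometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipelines for cortical hemodynamic imaging in rodents:
    temporal laser speckle contrast flowmetry with motion-frame rejection and
    static-phantom beta calibration, stimulus-evoked neurovascular-coupling
    quantification (window downsampling, top-fraction responder selection,
    baseline-normalized percent change, peak/AUC/time-to-peak metrics), and
    confocal vessel morphometry (maximum intensity projections, consensus
    reader ROIs, iterative-selection thresholding, size filtering,
    skeletonization, vessel density and mode-normalized diameter
    distributions). Includes synthetic-data generators with known ground
    truth (dynamic speckle with a chosen field correlation time, vessel
    phantoms with known geometry, evoked-response trial sets) and the group
    comparison statistics used on the pipeline outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
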