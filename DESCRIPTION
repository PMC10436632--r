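Package: diaflow
Title: Optical-Flow Tracking of Diaphragm Motion in Ultrasound Cine Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tracking of diaphragm deformation in B-mode
    ultrasound cine loops. Segments the bright diaphragm band in the first
    frame, seeds random tracking points filtered by density clustering
    (DBSCAN), follows them with a pyramidal Lucas-Kanade optical-flow
    tracker, and derives inter-frame and cumulative displacement curves,
    global strain, the respiratory period, and drift-corrected outputs.
    Includes a synthetic speckle-phantom generator with exact ground-truth
    motion and strain so the whole pipeline can be validated without
    patient data, a minimal multi-frame DICOM reader, and a command-line
    entry point.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
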