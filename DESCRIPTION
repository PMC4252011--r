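Package: epidArcQA
Title: EPID-Based Mechanical Quality Assurance of Linac Gantry, Imager and
    MLC Carriages During Arc Deliveries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses megavoltage portal images of a five ball-bearing
    phantom acquired during linac arc deliveries to quantify, in a single
    run, the gravity-induced sag of the imaging panel (EPID) and of the
    gantry head, changes in source-to-detector distance, panel/collimator
    skewness and panel tilt, and the bulk sag of the two multileaf-collimator
    carriages. Provides a minimal DICOM RT Image reader and writer, sub-pixel
    ball-bearing and field-edge detection with conservative smoothing and
    rank filtering, per-angle deformation metrics relative to the gantry-zero
    reference, TG-142 style tolerance reports, and a forward simulator of
    arc acquisitions under a parametric machine-deformation model that
    serves as ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, QualityControl, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'constructors.R'
    'detect.R'
    'dicom.R'
    'epidArcQA-package.R'
    'imaging-io.R'
    'metrics.R'
    'preprocess.R'
    'render.R'
    'report.R'
    'simulate.R'
    'utils.R'
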