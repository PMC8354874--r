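Package: contactprint
Title: Catheter Contact-Print Morphometry and Force-Area Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the contact footprint of an ablation
    catheter tip on heart-muscle tissue from binary contact-print images.
    Implements the image-analysis chain (grayscale conversion, Otsu or
    fixed-threshold binarization, pixel-calibrated area measurement,
    centroid alignment and principal-axis rotation, replicate occupancy
    averaging) together with moment-based shape descriptors and a
    four-class footprint typing (rectangular, semi-ellipsoidal, circular,
    ellipsoidal). A logarithmic force-area model (area = a*ln(force) + b)
    is fitted per tip shape and contact angle, with percentage contact
    area and gram-force/Newton conversions. A seeded synthetic
    contact-print generator reproduces the study design (2 tip shapes x
    5 contact angles x 8 contact forces x 6 replicates) so the whole
    pipeline is testable end to end; reference tables of published mean
    contact areas are bundled as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'contactprint-package.R'
    'laws.R'
    'model.R'
    'morphology.R'
    'study.R'
    'synthetic.R'
    'tips.R'
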