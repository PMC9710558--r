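Package: SeminifR
Title: Segmentation, Staging and Spatial Statistics for Seminiferous
    Tubule Immunofluorescence Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated analysis pipeline for multiplexed
    immunofluorescence images of mouse testis cross-sections. Provides
    top-hat intensity normalization, instance segmentation of nuclei and
    seminiferous tubules, residual convolutional network classifiers for
    seven germ-line/somatic cell types and the twelve cyclic tubule
    stages, confidence filtering, nuclear morphometrics (apical-basal
    position, relative orientation, nearest-neighbour networks,
    spermatogenic index, tubule and lumen radii), and a
    three-dimensional quantile normalization for batch-effect removal.
    A seeded synthetic-section generator with exact ground truth makes
    every stage of the pipeline testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Classification, Spatial
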