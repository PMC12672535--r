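Package: lymphomorph
Title: Lymph Node Phantom Morphometry, Slice-to-Volume Registration and
    Proteomic Abundance Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for whole-organ lymph node imaging
    studies: synthetic lymph-node phantom volumes with an eleven-class
    anatomical label map, micro-CT style stack conditioning and electron
    micrograph flat-field/stitch/invert preprocessing, mutual-information
    driven 2D-to-3D virtual-slice registration with coarse-to-fine
    coordinate descent, compartment morphometry (connected components,
    3D Feret diameters with shrinkage correction, sphericity, capillary
    density ratios, volume fractions), and adaptive differential-abundance
    statistics for bulk proteomes including single-sample and pre-ranked
    gene set enrichment.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
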