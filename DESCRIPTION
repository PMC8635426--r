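Package: histoquant
Title: Quantitative Image Analysis of Histology and Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the image-quantification
    computations used in wound-healing and graft-remodeling studies:
    Beer-Lambert colour deconvolution of Masson's trichrome sections with a
    fixed stain matrix, per-cell immunofluorescence quantification (automated
    DAPI thresholding, fixed marker thresholds, size-filtered nucleus
    counting), multicolour clonal-proliferation analysis by connected-component
    area, collagen fibre-alignment statistics on axial orientations (structure
    tensor, mean resultant length, Rayleigh test), box-counting fractal
    dimension, and manifest-driven batch orchestration with group statistics.
    A seeded phantom generator produces every input class with machine-readable
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
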