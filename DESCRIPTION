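Package: mosaicCT
Title: Fast Large-Volume Mosaic Micro-CT: Planning, Reconstruction, Stitching and Airway Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for wide-field (extended field of view, 360-degree)
    synchrotron micro-CT mosaics of soft tissue. Plans zigzag tile
    acquisitions and predicts their duration, simulates parallel-beam
    projection data of foam-like lung phantoms (illumination drift,
    propagation-based edge enhancement, Poisson noise, slow tissue
    deformation), performs dark/flat correction including dynamic
    principal-component flat-fielding, Paganin single-distance phase
    retrieval, filtered back-projection with offset rotation axes and
    per-layer center interpolation, non-rigid stitching of tile volumes
    with an overlap standard-deviation map, and a four-step airway
    segmentation with volume quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
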