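Package: intervox
Title: Interval-Coded Spatial Domains for Embryo Atlas Informatics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Run-length (interval) coding of binary 2D/3D spatial domains with
    fast set and morphological algebra; spatial similarity search over mapped
    gene-expression patterns (Jaccard and local spatial similarity scoring);
    syn-expression discovery by hierarchical clustering of pairwise-similarity
    signatures with per-node occupancy heatmaps; landmark-based piecewise-affine
    mapping of 2D assay images into reference model frames with colour-threshold
    signal extraction; arbitrary-plane virtual sectioning of annotated 3D
    volumes with RGBA overlay compositing and tiling; plus readers and writers
    for the exchanged artifacts (interval-domain JSON, NIfTI volumes, PNG
    masks and renders, pattern manifests) and seeded synthetic fixture
    generators.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    png,
    deldir,
    ape,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
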