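Package: hyperseg
Title: Semi-Supervised Hyperspectral Image Segmentation with Regularized
    LDA and Seeded Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised multilabel segmentation of hyperspectral
    images from a small set of user-marked seed regions.  The marked
    pixels drive a regularized linear discriminant projection of the
    spectral cube to a low-dimensional feature image; stacked
    neighborhood (patch) features define a spectral/spatial similarity
    index which weights both a per-pixel similarity to each seed class
    and the edges of a pixel graph; per-class membership probabilities
    are obtained by solving the combinatorial Dirichlet problem of the
    seeded random walker on that graph; the final label maximizes a
    convex log-combination of similarity and walker probability.
    Includes segmentation quality metrics (Rand index, overall
    accuracy, purity), ENVI/CSV raster input and output, and a
    synthetic scene generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Matrix,
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
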