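Package: sphereInsight
Title: Image-Based Classification of Zero-Inflated Compositional Count Data
    on the Hypersphere
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying zero-inflated, high-dimensional
    compositional count tables (OTU/ASV-style microbiome data). Counts are
    closed to the simplex, mapped to the unit hypersphere by the square-root
    transform, projected to the tangent space at the Fréchet mean by
    principal geodesic analysis, rendered as images by a DeepInsight-style
    feature layout with a segmentation offset that gives all sample images a
    common foreground support, and classified with a cross-validated
    convolutional network. Includes a zero-inflated Dirichlet-multinomial
    simulator with known class signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    kernlab,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'cnn.R'
    'classification.R'
    'compositional.R'
    'imaging.R'
    'pipeline.R'
    'sphere-geometry.R'
    'synthetic-data.R'
    'tabular-io.R'
    'tsne.R'
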