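Package: fractalens
Title: Multiscale Fractal Features and Classifier Ensembles for Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies RGB histology images with multiscale, multidimensional
    fractal techniques (fractal dimension, lacunarity and percolation computed
    from gliding-box probability matrices with Hoshen-Kopelman cluster
    labeling), generates Grad-CAM and LIME explanation representations from a
    pluggable classification backend and quantifies them the same way, builds
    enumerated ensembles of handcrafted, deep-learned and explanation-derived
    feature vectors, selects features per cross-validation fold with ReliefF,
    and classifies with a four-algorithm probability-averaging ensemble.
    Includes a seeded synthetic texture generator and a deterministic mock
    backend so the whole pipeline runs without external image sets, plus
    Friedman-test comparison of feature-vector categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    e1071,
    randomForest,
    caret,
    foreign,
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
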