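Package: acroshape
Title: 3D Surface-Mesh Morphometry and Classification of Sperm Acrosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for semi-automatic morphological classification of
    closed triangular surface meshes such as 3D-reconstructed sperm
    acrosomes. Reads and writes PLY, OBJ and legacy VTK polydata meshes;
    estimates discrete Gaussian and mean curvature; extracts a 7-parameter
    morphometric feature vector (volume, surface area, sphericity, average
    mean and Gaussian curvature and their relative fluctuations);
    characterizes two-class shape populations with Kolmogorov-Smirnov tests,
    log-space transforms and the surface-volume scaling law; and classifies
    individual shapes with a repeated cross-validated linear support vector
    machine scored by a per-cell/per-class accuracy framework, with a
    random-forest imbalance comparison. Includes a synthetic two-class shape
    population generator for end-to-end testing without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
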