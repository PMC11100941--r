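Package: NeuralSDF
Title: Neural Shape Models for Paired Bone and Cartilage Surfaces
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implicit neural shape modeling of paired anatomic surfaces
    (femoral bone plus overlying cartilage) via signed distance functions.
    Provides mesh geometry utilities (similarity registration, unit-sphere
    normalization, signed distances, isosurface extraction, surface-distance
    metrics), blue-noise SDF sampling, three autodecoder architectures
    (triplanar hybrid explicit-implicit, deep MLP, and modulated periodic
    activation decoders) with curriculum-weighted clamped-L1 training and
    cyclically annealed latent regularization, test-time latent fitting and
    surface reconstruction, regional cartilage-thickness biomarkers with
    RMSE/SDD evaluation, latent-space clinical staging heads (ordinal
    consistent-rank-logits and binary classifiers, latent interpolation and
    classifier-vector traversal), and a seeded synthetic knee-shape generator
    with ground-truth thickness fields and consistent clinical-style labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
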