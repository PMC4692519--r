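Package: mist
Title: Multimodal Deformable-Mesh Segmentation of Subcortical Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised Bayesian segmentation of subcortical brain
    structures from co-registered multimodal MRI. A reference triangle mesh
    is deformed along its vertex normals; per-vertex mixtures of multivariate
    normal intensity-profile models with structured covariances are learned
    from unlabelled training images by MAP estimation with the discrete
    boundary displacement marginalised out, a Normal-Wishart shape model over
    vertex displacements is trained by conjugate updating, and new images are
    segmented by maximising the posterior over continuous displacements.
    Includes intensity normalisation, mesh/voxel conversion, evaluation
    metrics (Dice, mean mesh distance, volume correlation) and a seeded
    synthetic multimodal phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
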