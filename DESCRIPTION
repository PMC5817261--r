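Package: petlesion
Title: Whole-Body PET/CT Bone-Lesion Detection with Volumetric Neural
    Networks and Digital Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end testbed for automated detection of multiple-myeloma
    bone lesions on hybrid PET/CT imaging. Provides a procedural whole-body
    digital-phantom generator (CT, anatomical labels, tracer activity,
    randomized skeletal lesions), a realistic PET measurement simulator
    (attenuated parallel-beam forward projection, analytic scatter and
    randoms expectations, Poisson noise, MLEM reconstruction), V-Net and
    cascaded W-Net volumetric segmentation networks trained with a
    class-weighted cross-entropy loss and a patch-balancing scheme,
    classical voxel-classifier baselines (random forest, k-nearest
    neighbours, linear SVM) on patchwise intensity features, and voxelwise
    plus lesionwise patch-overlap evaluation metrics with cross-validation
    helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    randomForest,
    e1071,
    class
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
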