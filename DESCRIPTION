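Package: orthoreg
Title: Non-Rigid 2D/3D Image Registration from Orthogonal Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep-learning based non-rigid 2D/3D image registration for lung
    tumour tracking. From two orthogonal X-ray-like projections and a moving
    3D volume, a convolutional registration network predicts a dense 3D
    deformation field that aligns the moving volume with the (unseen) anatomy
    at the projection moment. Includes the full training-data synthesis chain
    (multi-resolution demons inter-phase registration, thin-plate-spline
    intra-phase perturbations, hybrid random-weight superposition, parallel
    and cone-beam digitally reconstructed radiograph generation), a synthetic
    breathing-lung 4D phantom with analytic ground-truth deformations and
    landmarks, differentiable Dice / mutual-information / smoothness training
    losses, and an evaluation suite (Dice, 95% Hausdorff surface distance,
    normalized cross-correlation, mutual information, mean target
    registration error, tumour centre-of-mass error). All network layers run
    on the CPU with hand-derived backward passes; no external deep-learning
    framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
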