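Package: dirgan
Title: Multi-Scale Adversarial Deformable Registration for Longitudinal CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Unsupervised deformable image registration of longitudinal
    cone-beam CT (CBCT) volumes with a two-stage (global plus local)
    adversarially regularized spatial transformer. Provides the
    modality-independent neighbourhood descriptor (MIND) similarity loss,
    first/second-derivative displacement-field regularization, patch-wise
    inference with tiling and averaging, a synthetic abdomen phantom
    generator with ground-truth deformations, and a registration quality
    evaluation suite (target registration error, masked MAE and NCC, bony
    Dice, Jacobian-determinant regularity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
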