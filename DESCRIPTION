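Package: egaunet
Title: Lightweight Generative-Adversarial U-Net for Multi-Organ Segmentation
Version: 0.1.0
Authors@R:
    person("EGAUNet", "Maintainers", email = "egaunet@example.org", role = c("aut", "cre"))
Description: Reference implementation of EGAUNet, a lightweight encoder-decoder
    network for multi-organ segmentation of 2D medical images (abdominal MRI
    slices with liver, kidney and spleen labels). The encoder stacks ghost
    bottlenecks, skip connections carry a Global Spatial-Channel Attention
    block, and the decoder is built from Efficient Mapping Convolutional
    Blocks with an ECA-style channel gate. Training combines a supervised
    cross-entropy/Dice loss with a generative-adversarial term scored by a
    ghost-bottleneck discriminator. The package ships its own reverse-mode
    automatic differentiation over 4-D arrays (BLAS-backed im2col convolution
    kernels), multi-class segmentation metrics, DICOM/PGM readers, a seeded
    synthetic phantom generator, model profiling (parameters, size, FLOPs),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
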