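Package: padnet
Title: Perturbed and Adversarial Dreaming for Unsupervised Representation Learning
Version: 0.1.0
Authors@R:
    person("padnet", "developers", email = "padnet@example.org", role = c("aut", "cre"))
Description: Implements a three-phase wake-sleep training algorithm in which a
    convolutional encoder/discriminator and a generator learn representations of
    32x32 RGB images without labels. A Wake phase optimizes image reconstruction,
    a latent Kullback-Leibler regularizer and a real/fake discriminator; an NREM
    phase replays stored latent activities through the generator, occludes the
    generated images with random gray patches and trains the encoder to recover
    the stored latents (perturbed dreaming); a REM phase generates images from
    convex combinations of current and previous latent memories mixed with
    Gaussian noise and trains encoder and generator adversarially via a gradient
    sign switch (adversarial dreaming). Includes an episodic two-slot latent
    memory, sleep-pathology ablations, a procedural labeled shape-image generator,
    readers for the CIFAR-10 binary and SVHN cropped-digit MAT formats, and a
    representation-quality evaluation suite: linear readout separability, occlusion
    robustness curves, PCA projections, latent distance ratios and the Frechet
    distance between feature statistics of real and generated images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
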