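Package: swindiff
Title: Denoising Diffusion Synthesis of 2D Medical Images with a Swin-Transformer Denoiser
Version: 0.1.0
Authors@R: person("swindiff", "maintainers", email = "maintainers@swindiff.invalid", role = c("aut", "cre"))
Description: A denoising diffusion probabilistic model (DDPM) for synthesising
    2D grayscale medical images (chest x-ray, cardiac MRI, CT) and toy
    phantoms. Provides the full diffusion mathematics (linear variance
    schedule, closed-form forward marginal, Bayes posterior, learned-variance
    reverse process, hybrid noise-MSE + variational-lower-bound objective), a
    U-shaped denoiser mixing residual convolutional blocks with
    shifted-window self-attention blocks implemented on a small reverse-mode
    tape, an AdamW training loop, spaced-timestep ancestral sampling, and a
    generative-model evaluation suite (Inception score, Frechet distance,
    feature-distribution KL on a 2D t-SNE embedding, and a nearest-SSIM
    diversity score). Includes seeded anatomy-like phantom generation, PNG
    and NIfTI readers/writers for single-slice grayscale data, and a command
    line interface with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
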