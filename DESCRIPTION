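Package: noise2average
Title: Iterative Self-Supervised Denoising of Multi-Repetition MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoises multi-repetition volumetric MRI without clean reference
    data using an iterative residual-learning strategy: a convolutional
    denoiser is fine-tuned to map each noisy repetition to its residual
    against the repetition average (iteration 1) or the previous iteration's
    denoised output (later iterations), and the per-repetition denoised
    volumes are averaged at every iteration. Includes a compact 3D
    convolutional network (modified U-Net without pooling) with masked-loss
    training, block extraction and overlap-averaged reassembly, structural
    and diffusion-tensor phantom generators with affine-misalignment and
    Gaussian/Rician noise simulation, an ordinary-least-squares diffusion
    tensor toolbox with encoding-scheme design by condition-number
    minimization and electrostatic repulsion, and masked image-quality
    metrics (MAE, PSNR, SSIM) plus an unsupervised mean-squared-error
    stopping criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
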