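Package: nsstkad
Title: Ultrasound Image Denoising with Nonsubsampled Shearlets and
    Kernel Anisotropic Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Speckle and Gaussian noise suppression for grayscale medical
    ultrasound images. Decomposes an image with a shift-invariant
    (nonsubsampled) shearlet transform, applies scale-weighted adaptive hard
    thresholding to the directional high-frequency subbands, and smooths the
    low-frequency subband with an edge-preserving anisotropic diffusion whose
    conductivity is computed from distances in a Gaussian-kernel feature
    space. Includes comparison baselines (Laplacian-pyramid nonlinear
    diffusion, plain shearlet thresholding, image-domain kernel diffusion,
    median filtering), PSNR/SSIM/EPI image-quality metrics, a synthetic
    kidney-phantom and textured test-image generator, a benchmarking sweep,
    and helpers for treatment-effectiveness rates from stone-outcome counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
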