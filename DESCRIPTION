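Package: mrisr
Title: Super-Resolution and Beam-Tracking Simulation for Real-Time MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for increasing the spatial resolution of real-time MRI used
    in MRI-guided radiotherapy. Builds paired low/high-resolution training data
    by k-space truncation, trains an EDSR-style single-channel residual
    super-resolution network with an edge-weighted L1 loss (with bicubic and
    nearest-neighbour baselines), evaluates reconstructions with masked
    full-reference metrics (NRMSE, SSIM, PSNR) after rigid registration, and
    quantifies end-to-end latency and latency-corrected geometric tracking
    error of a multi-leaf-collimator tracking chain on simulated motion-phantom
    cine series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    EBImage
Suggests: testthat (>= 3.0.0), png, withr
Config/testthat/edition: 3
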