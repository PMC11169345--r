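Package: rflsm
Title: Ray Tracing and Image Analysis for Remote-Focusing Light-Sheet
    Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for a polarization-split remote-focusing
    (axially de-scanned) light-sheet fluorescence microscope. Provides
    paraxial ABCD ray tracing of the folded detection path (effective focal
    lengths, lateral magnification versus scan position, S/P image
    separation, geometric collection efficiency), sub-pixel S/P image
    registration by scaled cross-correlation with polynomial peak
    interpolation, bead-based point-spread-function and light-sheet
    characterization (Gaussian FWHM fitting, tilt-corrected waist and
    field-of-view estimation), parallel-line calibration-target
    magnification estimation, a dual-color live-cell processing pipeline
    (drift correction, channel registration, Richardson-Lucy deconvolution,
    isotropic resampling, quantile normalization), mean-square-displacement
    analysis of granule trajectories (diffusion/velocity fitting and motion
    classification), and seeded synthetic-data generators with ground truth
    for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
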