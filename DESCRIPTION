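Package: sonifluor
Title: Auditory Display of Hyperspectral Fluorescence Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts in vivo near-infrared fluorescence (NIRF) hyperspectral
    image cubes into sound. Region-of-interest spectra are reduced to a
    probe-to-background ratio that drives the modulation index of a
    two-oscillator FM synthesizer, yielding per-ROI audio, an audio spectrum,
    a waveform and a numeric value; per-pixel ratios are rendered back into
    rainbow-scale parametric images. Includes a synthetic tumor-phantom
    generator with ground truth, rank-based group comparison of ROI ratios,
    and a command-line pipeline (phantom, probe, map, stats).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tiff,
    png,
    EBImage,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
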