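Package: trivarmap
Title: Perceptually Uniform Tri-Variate CIELAB Color Coding for
    Multiparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds linear, perceptually uniform three-dimensional color
    maps in CIELAB space from eight anchor colors and uses them to fuse
    three co-registered parametric MRI channels (for example b800
    diffusion, ADC and a perfusion map) into a single false-color image.
    Includes per-channel preprocessing (quantile winsorization,
    normalization, percentile contrast stretching, resampling to a
    reference grid), alpha blending over an anatomical underlay,
    CIELAB delta-E contrast analysis between tumor and non-tumor regions
    of interest, segment-level diagnostic-accuracy metrics (sensitivity,
    specificity, PPV, NPV) from contingency counts, seeded synthetic
    phantoms for end-to-end testing, NIfTI/PNG input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    jsonlite,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
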