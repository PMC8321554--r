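Package: actinpatches
Title: Quantification of Presynaptic Actin Patch Dynamics from Timelapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify discrete, transient actin assembly events
    ("patches") at presynaptic terminals from fluorescence timelapse movies.
    Implements sub-pixel Laplacian-of-Gaussian spot detection with a
    probe-normalized threshold, globally optimal frame-to-frame linking,
    patch frequency/duration/amplitude statistics with a merged
    two-sampling-rate frequency estimator and correction bounds, a
    tracking-free per-pixel coefficient-of-variation dynamics statistic with
    Li and Moments automatic thresholding, a simulation-based calibration
    that converts coefficient-of-variation differences into inferred
    patch-frequency changes, and a synthetic-movie generator with ground
    truth used for validation and calibration. Also provides masked Pearson
    colocalization and FRAP double-normalization with recovery fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
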