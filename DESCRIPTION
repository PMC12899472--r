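Package: tremorcam
Title: Contactless Tremor Quantification from Video with Accelerometer
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies pathological tremor (essential and dystonic tremor,
    2-12 Hz) from ordinary 2D video without markers or wearables. Consecutive
    frames of a fixed rectangular region of interest are differenced, the
    intensity-weighted centre of mass of each difference image yields a
    motion time series, and Welch spectral analysis of that series gives the
    peak tremor power (dB) and peak power frequency (Hz). A parallel pipeline
    derives the same metrics from 3-axis accelerometer recordings, and
    agreement between the two modalities is quantified with two-way random
    effects single-measure consistency intraclass correlation (with
    Fleiss-Shrout confidence intervals), mean absolute error and
    Bland-Altman analysis. A synthetic-scene generator (oscillating blobs
    with noise and rolling-shutter flicker banding, plus matched synthetic
    accelerometry) provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
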