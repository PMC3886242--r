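Package: fsvps
Title: Functional Single-Voxel Proton Spectroscopy Feedback Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting a BOLD-sensitive feedback signal from
    unsuppressed-water single-voxel proton spectroscopy (SVPS) acquisitions.
    Each free-induction decay (FID) frame is conditioned by water-peak
    frequency shifting and Gaussian spectral windowing, and an apparent T2*
    is estimated by complex log-linear regression over an optimisable early
    segment of the decay. The per-repetition T2* series is turned into a
    real-time feedback value by exponential-moving-average drift removal, a
    spike-rejecting scalar Kalman filter, and incremental range
    normalisation. Session quality is scored with contrast-to-noise ratio,
    percent signal change, block-design GLM t-values, and event-related
    averages. A synthetic 7 T spin-echo SVPS session simulator with ground
    truth makes every stage testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
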