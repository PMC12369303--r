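Package: cthair
Title: Quantification of C-Tactile Afferent Responses to Hair Deflection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike-train quantification, unit classification and stimulus
    coupling analysis for human microneurography studies of C-tactile (CT)
    afferents and hair follicle afferents. Implements extracellular spike
    detection with template matching, instantaneous-frequency metrics,
    monofilament threshold estimation, after-discharge quantification
    following hair plucking, M-mode optical coherence tomography surface
    tracking with windowed micro-displacement estimation and Tukey HSD
    condition comparison, dense polynomial-expansion optical flow with
    cumulative displacement fields, and curvature-based instrument tip
    tracking. All stages are driven by synthetic-data generators with known
    ground truth so the full pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
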