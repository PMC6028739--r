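Package: astroquant
Title: Quantitative Morphology and Activity Analysis of Astrocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for quantifying astrocyte morphology and
    activity in fluorescence imaging and slice electrophysiology. Provides a
    cone-adapted Meyer-type shearlet decomposition with per-pixel spatial
    entropy and statistical complexity maps (Jensen-Shannon disequilibrium),
    automated Sholl intersection profiling on adaptively thresholded
    projections, leaflet volume-fraction estimation from fluorescence line
    profiles, gap-junction dye-coupling decay fits, x-y-time calcium event
    detection with power-law exponent estimation by log-binning, and
    whole-cell / field-potential metrics (potassium current decay, fEPSP
    slope, paired-pulse ratio, Gompertz input-output fits, LTP magnitude).
    A synthetic-data module generates every input with known ground truth so
    each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
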