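Package: htrfscreen
Title: Dual-Cytokine HTRF High-Throughput Screening Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 384-well homogeneous time-resolved
    fluorescence (HTRF) cytokine screens with a dual IL-1beta/IL-6 readout:
    conversion of raw two-channel emissions to HTRF ratios, control-anchored
    percent-inhibition normalization with a mean +/- 3SD outlier rule,
    per-plate quality control (Z'-factor and signal-to-background ratio),
    a staged hit-triage cascade (primary IL-1beta threshold, IL-6
    counter-screen band, steroid and duplicate exclusion), four-parameter
    logistic dose-response fitting with IC50 estimation and an
    interpolation fallback, and per-dose IL-1beta-predominance calls for
    confirmation. Includes a seeded synthetic-screen generator with known
    ground truth, calibrated so that plate statistics reproduce a
    stimulated-macrophage inflammasome screen.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
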