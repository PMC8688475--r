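Package: photometr
Title: Scriptable Fiber Photometry Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless pipeline for bulk fluorescence (fiber photometry)
    recordings: reads two-channel sessions (calcium-dependent signal plus
    isosbestic control) from per-channel or interleaved CSV files, denoises
    with a zero-phase moving-average filter, excises artifact-contaminated
    segments while preserving behavioral timestamp alignment, computes
    dF/F against a least-squares fitted control (or an exponential
    bleaching pseudo-control when no isosbestic channel was recorded),
    standard/baseline/modified z-scores, whole-session calcium transient
    statistics via a two-stage median-absolute-deviation threshold,
    peri-event time histograms with per-trial baseline correction and
    AUC/peak window measures, and equal-weight group averages across
    sessions.  Includes a ground-truth synthetic session generator so the
    full pipeline is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
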