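Package: xicquant
Title: Targeted Mass-Spectrometry Quantification with SNIP Baselines and
    Extracted Ion Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for targeted hyphenated mass-spectrometry
    analysis. Reads delimited chromatography traces with automatic dialect
    detection and MS1 runs from mzML, corrects chromatographic baselines with
    the SNIP algorithm (statistical non-linear iterative peak clipping in
    log-log-square-root compressed space), builds ppm- or dalton-windowed
    extracted ion chromatograms with grouped binary search over sorted m/z
    arrays, integrates peaks around retention-time anchors with a trapezoidal
    fallback, fits linear or log-log calibration curves, estimates compound
    concentrations, and exports long-format CSV results. Ships a deterministic
    synthetic-data generator (chromatograms, centroided MS1 runs, calibration
    series, minimal mzML writer) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
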