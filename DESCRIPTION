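Package: respyre
Title: Respiratory Rate Estimation from Photoplethysmography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates respiratory rate (breaths per minute) from a
    single-channel photoplethysmogram (PPG). The pipeline interpolates
    missing samples, band-pass filters the signal, enhances pulse peaks,
    removes outliers with a Hampel filter, gates windows on an
    entropy-based signal quality index, detects systolic peaks with a
    moving-average threshold, rejects false peaks, and extracts the
    respiratory frequency from the inter-beat-interval power spectrum by
    a Welch estimator restricted to the 0.1-0.4 Hz respiratory band.
    Includes windowed evaluation against reference rates (MAE/RMSE),
    best-window calibration, readers for generic and paired
    signals/numerics CSV layouts, and a seeded synthetic PPG generator
    with known respiratory ground truth and controllable artefacts
    (spikes, dropouts, clipping, baseline wander).
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
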