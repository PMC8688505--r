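Package: microdyn
Title: EEG Microstate Dynamics and Task-Related Band Power for Open-Ended
    Task Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying large-scale brain network dynamics in
    multichannel EEG recorded during self-paced cognitive tasks. Implements
    task-related band power (Welch spectra, trapezoidal band integration,
    log-power change from a resting reference, region-by-hemisphere
    aggregation and repeated-measures statistics), polarity-invariant EEG
    microstate segmentation (modified k-means on global-field-power peak
    topographies, cross-validation model selection, group map alignment,
    back-fitting, and duration/occurrence/coverage statistics), and
    information-theoretic temporal dynamics of microstate label sequences
    (finite entropy rate, autoinformation function with first-peak latency,
    and detrended fluctuation analysis Hurst exponents averaged over all
    3-vs-4 class bipartitions). A synthetic-EEG module plants known
    microstate structure and sequence statistics so that every stage of the
    pipeline can be validated against ground truth, and a study-level
    driver runs the full chain from raw recordings to cohort statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
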