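Package: lmiscreen
Title: Serum Low-Mass-Ion Discrimination Screening for Cancer Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based screening of low-mass-ion (LMI) peak tables from
    untargeted serum LC-MS profiling. Implements single-ion discrimination
    threshold search on a fixed 0.01 grid with tie-averaging, perfect-separation
    gaps and Fisher's discriminant ratio ranking; exhaustive ordered dual-ion
    screening under ratio-of-logs and log-of-ratio pair scores; total-area-sums
    normalization and the log10 transform with the zero-area rule; Shapiro-Wilk
    gated two-group comparisons (Welch t-test or Mann-Whitney U); and a
    synthetic cohort generator with planted single-ion and pair markers so the
    whole pipeline is testable without raw spectra.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
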