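Package: reefpam
Title: Passive Acoustic Monitoring Analysis of Coral Reef Soundscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring (PAM) of coral reef
    soundscapes: calibrated recovery of sound pressure (micropascal) from
    hydrophone WAV recordings, band-specific power spectral density (PSD)
    estimation with Kaiser-windowed short-time FFTs, extraction of the peak
    level (PSD_Fpeak) and peak frequency (gammaFpeak) of median spectra per
    site, calendar day and diel period, a 3 dB instrument-error significance
    margin, and a statistical layer of mixed-effects ANCOVA with type-II Wald
    chi-square tests and canonical correspondence analysis. Includes a
    synthetic soundscape generator (snapping-shrimp transient trains, fish
    choruses, power-law ambient noise, diel cycles and group-level offsets)
    for validating the full pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    car,
    vegan,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
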