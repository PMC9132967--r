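Package: muerg
Title: Multiscale Entropy Analysis of Retinal Micro-Electroretinogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the complexity of retinal micro-electroretinogram
    (uERG) recordings using multiscale entropy. Implements sample entropy
    and fuzzy entropy, coarse-graining, composite and refined composite
    multiscale entropy (CMSE/RCMSE), and a cumulative complexity index over
    a fixed scale window, together with the surrounding analysis pipeline:
    trial averaging, 30 Hz low-pass filtering and decimation to 200 Hz,
    Welch power spectral density and magnitude-squared coherence, and
    nonparametric (Mann-Whitney U) group comparisons of complexity indices.
    A synthetic-data module generates calibrated uniform and 1/f (pink)
    noises, chirp and natural-like luminance stimuli, surrogate uERG trial
    sets, and labeled multi-group cohorts with controllable complexity
    differences, so the whole pipeline can be exercised and validated
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
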