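Package: ecgnoise
Title: Robustness of ECG Image-Transform Classifiers to Physiological Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how physiological noise on the
    electrocardiogram (ECG) affects image-transform classification. Generates a
    labelled synthetic three-class ECG cohort (atrial fibrillation, Normal,
    ST depression) and a 30-minute bank of baseline-wander, electrode-movement
    and motion-artefact noise; cleans raw records with a zero-phase filtering
    chain; injects noise at an SNR calibrated exactly to a target drawn in
    5-10 dB; converts lead-II signals to 150x150 symmetric projection attractor
    (SPAR) density images and analytic Morse wavelet scalograms; and evaluates
    classifier robustness across train/test noise conditions with per-class and
    macro F1 over predefined stratified cross-validation folds.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
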