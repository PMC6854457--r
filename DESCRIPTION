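Package: opmtheta
Title: Source Localisation of Hippocampal Theta Power Changes from
    Wearable OPM-MEG Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for optically-pumped
    magnetometer (OPM) magnetoencephalography studies of deep theta
    (4-8 Hz) sources. Generates epoched two-condition sessions from a
    conducting-sphere dipole forward model with structured environmental
    interference and a four-sensor reference array; suppresses
    interference by trial-wise reference regression (synthetic
    gradiometry); localises condition-dependent band-power changes with
    a scalar linearly-constrained minimum-variance (LCMV) beamformer;
    and performs group-level maximum-p conjunction inference with
    false-discovery-rate control plus bootstrap stability mapping of
    the significant clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
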