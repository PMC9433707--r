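Package: csepnet
Title: Objective Speech Intelligibility Prediction from EEG with
    Continuous Speech-Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for predicting behavioral speech
    intelligibility scores from multichannel EEG responses to continuous
    (noise-vocoded) speech. Provides a noise vocoder for generating
    spectrally degraded stimuli, stimulus feature extraction (temporal
    envelope, phoneme-onset impulse train and their product), EEG
    preprocessing and epoching, construction of event-related potential
    and continuous speech-evoked potential (CSEP) feature images by
    bootstrap averaging of per-lag cross-correlation coefficients,
    dataset augmentation (Gaussian noise, temporal cutout, sensor
    dropout), a compiled convolutional network classifier over 38
    discrete intelligibility levels, and occlusion-sensitivity
    attribution of the decision to scalp electrodes. A synthetic-study
    generator emulates the full experiment (vocoded conditions,
    psychometric scores, forward-modelled cortical tracking) so the
    pipeline is testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
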