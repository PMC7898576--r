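Package: pupilbeat
Title: Oscillator Models of Rhythmic Attention and Pupillometric Entrainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses deviance-detection experiments with looping
    rhythmic stimuli. Implements a linear-oscillator (reson filter bank) model of
    dynamic temporal attention that turns audio into time-resolved salience
    predictions, a pupillary-response-function forward model of the continuous
    pupil signal, a ZEST Bayesian adaptive threshold procedure with a simulated
    psychometric observer, pupillometry preprocessing and evoked pupil dilation
    response extraction, and a Welch cross-spectral phase-coherence entrainment
    analysis with a shuffled-stimulus null. Ships synthetic generators for
    rhythm patterns, rendered looping audio with scheduled intensity deviants,
    and raw eye-tracker-style pupil logs, so the full pipeline runs without any
    external recordings.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
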