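Package: eegselect
Title: EEG Emotion-Recognition Features and Swarm-Based Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for valence-arousal emotion recognition from multi-channel
    EEG trials. Implements a multi-domain feature bank (time-domain statistics,
    Welch band power, band-limited differential entropy, rational asymmetry
    over hemispheric electrode pairs, and db4 wavelet entropy/energy), wrapper
    feature selection by particle swarm optimization with constant,
    linearly-decreasing, and multi-stage linearly-decreasing inertia-weight
    schedules, a Relief filter baseline, and a leak-free nested
    cross-validation harness around a linear support vector machine. Includes
    a deterministic synthetic EEG generator with planted band-power effects so
    the whole pipeline can be exercised without external recordings, plus EDF
    and plain numeric interchange input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
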