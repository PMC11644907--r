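Package: wheelbci
Title: Motion-Artifact Correction and Classification for Wheelchair
    Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for removing wheelchair-motion artifacts from 8-channel
    motor-imagery EEG using an empirical error model calibrated from
    accelerometer data, tire-surface friction, subject weight, and
    wheelchair weight, and for classifying the corrected signals with a
    compact convolutional neural network. Includes reading and writing of
    OpenBCI-GUI-style delimited recordings, cue-locked epoching, channel
    averaging and restoration, Hjorth, statistical, wavelet and spectral
    feature extraction, a natively implemented 2-D CNN with batch
    normalisation and Adam optimisation, and a synthetic EEG+IMU generator
    with known ground-truth artifact structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
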