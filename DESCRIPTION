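Package: pupilstate
Title: Coupling of Phasic Pupil Dilations to Cortical EEG State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking pupil-linked arousal to cortical state:
    detection and peak-alignment of phasic pupil dilations (spontaneous and
    stimulation-evoked), sliding-window EEG band-power estimation on the pupil
    time grid, aperiodic (1/f-with-knee) spectral parameterization,
    window-based and pointwise coupling statistics, and band-wise
    classification of dilation type with a 1-D convolutional network and five
    baseline models under stratified cross-validation. A synthetic-data module
    generates pupil and EEG sessions with known ground truth so every stage of
    the pipeline is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    withr,
    glmnet,
    ranger,
    e1071,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
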