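Package: gazedecode
Title: Decoding Stimulus Orientation from Fixational Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A decoding-confound analysis pipeline for binocular eye-tracking
    experiments. Simulates fixational eye movements (microsaccades, drift,
    tremor), pupil dilation and blinks for grating-orientation experiment
    schedules, optionally injecting an orientation-coupled microsaccade
    confound as positive control; preprocesses raw 1000 Hz gaze recordings
    (blink imputation, zero-phase Butterworth low-pass, resampling to 256 Hz,
    trial slicing, per-run median centering); detects microsaccades with a
    velocity-threshold algorithm; computes per-trial summary-statistic
    features (means, standard deviations, eye-angle occupancy and
    microsaccade-direction histograms); decodes orientation under
    leave-one-run-out cross-validation with linear support vector machines,
    a 1-D convolutional network and an LSTM; and performs within-participant
    permutation tests and group-level zero-inclusive Wilcoxon signed-rank
    inference against chance level.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
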