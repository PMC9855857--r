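Package: emgfocus
Title: Attentional-Focus Recognition from Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising exercise type, attentional focus and lifted
    load (%1RM) from 8-channel surface electromyography recorded during
    free-weight strength training. Implements frame-energy movement
    segmentation, a 56-dimensional time- and frequency-domain feature
    representation (RMS, waveform length, mean absolute value, variance,
    thresholded zero crossings, modified median and mean frequency per
    channel), a multitask neural network with a task-output fusion layer for
    load recognition, one-vs-one RBF support vector machine and single-task
    network baselines, per-subject evaluation with majority voting, and
    RMS-based muscle-contraction contrasts across attention and load
    conditions. Includes a synthetic session generator producing
    burst-structured, amplitude-modulated band-limited Gaussian EMG with
    exercise-specific channel activation profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
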