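Package: convoscope
Title: Turn-Taking and Gaze Analysis for Face-to-Face Conversations in Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for triadic face-to-face conversation
    experiments with wearable eye tracking and close-talk microphones.
    Segments multichannel conversation audio into talker-attributed turns
    using energy-based voice activity detection with crosstalk rejection;
    classifies wearable eye-tracking streams into blinks, fixations and
    saccades (I-DT); post-processes area-of-interest bounding-box tracks and
    annotates gaze samples with their AOI; preprocesses pupillometry with
    per-face baselines; and computes turn-aligned gaze metrics (dwell times,
    onset/offset gaze latencies, first/last-fixation probabilities, saccade
    rate, fixation duration, pupil dilation). Includes a synthetic-trial
    simulator with exported ground truth so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
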