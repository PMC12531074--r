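# convoscope

Measurement pipeline for triadic face-to-face conversation experiments with
wearable eye tracking and close-talk microphones — the kind of paradigm
where three participants converse 1.5 m apart in controlled background
babble while 9 channels of audio (per participant: one close-mouth and two
in-ear microphones, 48 kHz), 50-Hz gaze/pupil streams, and 25-Hz
area-of-interest (AOI) detections from the scene video are recorded.

The package turns those raw streams into the per-trial features that
hearing-science analyses of conversational gaze are built on:

* **Speech segmentation.** Energy-based voice activity detection per
  close-mouth channel (100-Hz zero-phase high-pass; 20-ms RMS frames with
  50% overlap; a threshold between the two modes of the bimodal dB-RMS
  distribution via Otsu's method), crosstalk rejection by a 6-dB level
  rule, a cross-correlation lag-sign rule (±300 samples), and a 0.8-ms
  close-mouth/in-ear delay gate, then utterances (gaps < 180 ms merged,
  intervals < 90 ms removed, in that order) and talker-attributed turns
  (uninterrupted pauses merged, turns < 1 s excluded).
* **Eye events.** Trial exclusion above 30% missing data; blinks from
  binocular missing data plus pupillometry noise (50–1000 ms); angular
  conversion through the scene-camera pinhole model; 1000-deg/s velocity
  cull; Savitzky–Golay smoothing (order 5, window 9); interpolation of gaps
  < 200 ms; I-DT fixation/saccade classification (dispersion 1.5°, minimum
  100 ms); 200-ms moving-median pupil smoothing with per-face baselines.
* **AOI annotation.** Box-track post-processing (window-3 median, per-kind
  size clamps, < 4-frame false positives removed, < 50-frame gaps
  interpolated, 40-px ≈ 2° enlargement) and per-sample gaze labelling with
  face > task > person priority.
* **Turn-aligned metrics.** Dwell percentages per AOI and conversational
  state; onset/offset gaze latencies (median and IQR) and first/last
  fixation probabilities in ±4-s windows around turn boundaries, split by
  transition role (self-turn vs other-turn; next talker vs remaining
  listener); saccade rate, mean fixation duration, mean/max
  baseline-corrected pupil dilation; a tidy long feature table ready for
  mixed-model analysis (`value ~ condition * state + (1 | group/participant)`).

A synthetic-trial generator produces complete trials — 9-channel audio with
configurable crosstalk, seat-distance delays and diffuse 8-talker babble;
gaze as a fixation–saccade–blink process coupled to the turn script with
injected latencies; degraded AOI tracks; pupil traces with
condition-dependent dilation — together with exported ground truth, so
every stage is validated by parameter recovery. See the methods vignette
(`vignettes/pipeline-methods.Rmd`) for the model, every threshold, and the
design decisions.

## Worked example

```r
library(convoscope)

cfg <- trial_config(seed = 42, duration_s = 60, condition = "noise")
res <- run_trial(cfg)
writeLines(res$log)
#> trial G1/T1: condition=noise seed=42 duration=60s
#> segmentation: 15 utterances, 15 turns
#> P1: missing fraction 0.009 (keep)
#> P1: 4 blinks, 84 fixations, 83 saccades
#> P2: missing fraction 0.019 (keep)
#> P2: 8 blinks, 75 fixations, 74 saccades
#> P3: missing fraction 0.012 (keep)
#> P3: 5 blinks, 88 fixations, 87 saccades

head(res$turns)
#>   talker onset offset n_utterances
#> 1     P1  5.01  10.22            1
#> 2     P2 10.47  11.88            1
#> 3     P1 12.44  14.95            1
#> 4     P3 15.30  16.71            1
#> 5     P1 16.91  19.28            1
#> 6     P3 19.68  23.84            1

subset(res$features, participant == "P1" & state == "listening" &
       metric %in% c("dwell_people_pct", "dwell_task_pct",
                     "onset_median_latency_s", "saccade_rate_hz",
                     "mean_pupil_dilation_mm"))
#>    participant     state                 metric      value
#> 8           P1 listening         dwell_task_pct 18.4508816
#> 10          P1 listening       dwell_people_pct 80.6675063
#> 14          P1 listening onset_median_latency_s -1.8050000
#> 32          P1 listening        saccade_rate_hz  1.0705290
#> 36          P1 listening mean_pupil_dilation_mm  0.1532717
```

Reading the numbers: the detected turns match the simulation's scripted
turns to ~10–20 ms (the true first turn starts at 5.00 s, after the 5-s
pre-noise lead-in). While listening, P1 spends 80.7% of valid gaze samples
on the interlocutors (their person boxes, faces included) and 18.5% on the
task sheet. The negative median onset latency (−1.8 s) reflects the default
gaze script's anticipatory behavior — a listener is often already looking
at the upcoming talker when the turn starts. The mean pupil dilation of
+0.153 mm on face-directed samples recovers the +0.15-mm dilation the
generator injects in the noise condition.

`export_features(list(res))` flattens one or more trials into the long
table (group, participant, trial, condition, state, feature, value);
`write_intervals_csv()` and `write_textgrid()` export turns for inspection
in Praat. A thin CLI (`inst/cli/convoscope`) wraps the same functions:
`convoscope simulate --out DIR` writes a full synthetic trial (WAV, CSVs,
ground-truth JSON) and `convoscope run --config trial.yaml --out DIR` runs
a trial end-to-end.

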