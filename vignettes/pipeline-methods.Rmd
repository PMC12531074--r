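---
title: "Measuring gaze and turn-taking in triadic conversations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gaze and turn-taking in triadic conversations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convoscope)
```

## The measurement problem

In a triadic face-to-face conversation experiment, three participants sit
1.5 m apart, each wearing eye-tracking glasses (50-Hz gaze and pupil, 25-Hz
scene video at 1920x1080 over a 95 x 63 degree field of view), a close-mouth
microphone and two in-ear microphones, giving a 9-channel 48-kHz audio
recording per conversation. Background babble at one of two levels
("quiet"/"noise") manipulates communication difficulty. The scientific
questions — how gaze allocation, its coupling to turn-taking, and
load-related oculomotor/pupil markers change with noise — all rest on a
chain of measurement stages:

1. **Speech segmentation**: energy-based voice activity detection per
   close-mouth channel, crosstalk rejection, and the assembly of
   talker-attributed *turns*.
2. **Eye events**: blink detection, gaze preprocessing, I-DT
   fixation/saccade classification, pupil preprocessing.
3. **AOI annotation**: post-processing of per-frame bounding-box tracks for
   the interlocutors, their faces and the task sheet, and per-sample gaze
   labelling.
4. **Turn-aligned metrics**: dwell times, onset/offset gaze latencies,
   first/last-fixation probabilities, saccade rate, fixation duration, and
   baseline-corrected pupil dilation, split by conversational state and by
   turn-transition role.

This package implements that chain, plus a synthetic-trial generator with
exported ground truth so that every stage is testable by parameter recovery.
It deliberately stops at the tidy feature table: mixed-model inference on
real data is ordinary statistics (`lme4::lmer(value ~ condition * state +
(1 | group / participant))`) and is out of scope.

## Speech segmentation

The audio is high-pass filtered at 100 Hz to remove breathing noise. The
filter applies the squared magnitude response of a 4th-order Butterworth
high-pass in the frequency domain — the spectral equivalent of
forward–backward (`filtfilt`) filtering — so it is exactly zero-phase and
cannot shift interval boundaries. Channels are split into 20-ms rectangular
frames with 50% overlap and the per-frame RMS is computed.

The dB-RMS distribution of a close-mouth channel during conversation is
bimodal: background (plus attenuated crosstalk) versus the wearer's own
speech. The threshold between the modes is found with **Otsu's method** on a
64-bin histogram — a deterministic, standard two-class separator. Two
degeneracy guards trigger a fallback of `max - 6 dB` with a warning: a
dynamic range below 3 dB, and a between-class mean separation below 8 dB.
The second guard is the operative one for background-only channels: babble
modulation alone spreads frame levels over ~6 dB, so a pure range test does
not detect unimodality, but a genuine speech/background split separates the
class means by 20 dB and more while babble-only channels stay near 4 dB.
The 8-dB cut sits above the 6-dB crosstalk margin and well below any real
speech/background separation.

Crosstalk is removed from each participant's above-threshold frames by
three tests, in order:

1. **Level**: frames more than 6 dB below another talker's close-mouth
   level are crosstalk.
2. **Lag sign**: frames within 6 dB of a competitor are kept only if the
   peak cross-correlation lag (searched over ±300 samples on a ±100-ms
   context) says the participant's own channel leads — i.e. the signal
   originates closer to their microphone. The sign convention is pinned by
   a unit test on synthetically delayed signals.
3. **In-ear delay**: maximal retained segments whose peak close-mouth to
   in-ear delay magnitude is *below 0.8 ms* (about 30 cm of acoustic path)
   are removed. This rule is applied per contiguous segment, not per frame —
   which is also what makes it cheap (one lag estimate per segment).

The in-ear rule deserves a note. As stated, it removes *small* delays; but
a wearer's own mouth-to-ear path is short, so small close-mouth/in-ear
delays are exactly what genuine own speech produces. The physical intent is
ambiguous, so the package implements the rule as printed and exposes
`inear_rule = "below" | "above" | "off"` to invert or disable it. The
synthetic acoustic scene defaults its mouth-to-in-ear delay to 1.0 ms —
above the gate — so that ground-truth speech in simulations is unambiguous
under the printed rule; scenes with sub-gate delays can be configured to
study the rule's effect.

Speech intervals then become utterances and turns: gaps shorter than 180 ms
are merged **first**, intervals shorter than 90 ms are removed **second**
(the order is observable: a 50-ms fragment 100 ms away from a long interval
survives via merging; the reverse order would delete it, and a unit test
pins the implemented order). Consecutive same-talker utterances merge into
one turn when no other talker's (post-filter) utterance starts inside the
pause; turns shorter than 1 s are excluded as noise or backchannels. Whether
sub-90-ms (removed) speech should count as an interruption is undefined;
interruption is tested against post-filter utterances.

On synthetic 60-s trials at the study conditions (10-dB crosstalk
attenuation, quiet babble 30 dB below speech, no overlap), turn recovery is
one-to-one with boundary errors of ~10–20 ms, dominated by the 10-ms frame
hop and the syllabic envelope of the speech surrogate.

One stated invariant was inverted in implementation: with a fixed
threshold, *raising* the babble level can only add frames to the energy
mask (the noise floor rises), never remove them; the tests assert this
direction.

## Eye events

Trials with more than 30% invalid-or-absent samples (relative to the count
expected at 50 Hz over the span) are excluded. Blinks are maximal runs of
binocular missing data, extended over adjacent samples whose pupil diameter
jumps by more than 1 mm per sample (pupillometry noise at the lid edges),
and kept only if 50–1000 ms long; shorter runs are tracker dropouts and
longer runs are treated as data loss, both left unlabeled.

Gaze preprocessing, in order: blink/invalid/zero-position removal; pixel-to
angle conversion through the scene-camera pinhole model (95 degrees across
1920 px horizontally; the per-eye direction vectors carry the same angles
binocularly); a velocity cull at 1000 deg/s — a sample is culled when the
velocity both into and out of it exceeds the threshold, which removes
single-sample spikes without eating the flanks of genuine fast movements,
while the *reported* velocity is the central difference; Savitzky–Golay
smoothing (order 5, window 9) of the gaze location per contiguous valid
run; and linear interpolation of gaps shorter than 200 ms. Runs shorter
than the smoothing window are left unsmoothed and flagged. The
Savitzky–Golay filter is applied after reflection-padding each run by half
a window: the filter's own edge handling fits high-order polynomials to few
noisy points and produced spurious wiggles at blink boundaries, which
fragmented fixations.

Fixations come from the classic I-DT algorithm: a window is grown from the
minimum duration (100 ms) while its dispersion — horizontal range plus
vertical range — stays within 1.5 degrees; the centroid is the mean
position. Valid inter-fixation intervals are saccades; intervals containing
missing data are neither. The implementation is checked for exact equality
against an exhaustive window-growing oracle on thousands of random short
traces.

A practical note on boundary accuracy: the 9-sample (180-ms) smoothing
window spreads each saccadic transition over about ±2 samples, and I-DT by
construction absorbs transition samples that stay within the dispersion
bound. Detected fixation *boundaries* therefore carry a systematic ~2-sample
bias relative to scripted ground truth even at zero measurement noise; the
recovery tests assert boundaries within four sample periods (80 ms) for 95%
of fixations that are long enough (≥ 250 ms) and not clipped by a blink,
and that is the realistic accuracy users should expect at 50 Hz. Scripted
fixations shorter than ~200 ms, or fixations overlapping blinks longer than
the interpolation bridge, are not reliably separable at this sampling rate.
Sample-based latency metrics (below) do not inherit this bias because AOI
entry/exit is decided per sample, not per fixation.

Pupil diameter is the mean of the two eyes where both are valid. Blink
samples are removed, a 200-ms moving median (shrinking at the trace ends)
suppresses single-sample artefacts, and remaining missing runs are linearly
interpolated; the pre-interpolation validity mask is kept.

## AOI annotation

The AOI tracks (faces, persons, task sheet; 25 Hz) are consumed as bounding
boxes — the video detectors themselves are upstream of this package. Per
(kind, identity) track, in order: a window-3 moving median over x, y, w, h;
a size clamp (valid widths 50–300 px for faces, 50–900 px for persons,
100–1400 px for task material; the ranges are interpreted on box *width*,
configurable, since the source does not say which dimension); removal of
presence runs shorter than 4 frames (false positives); linear interpolation
of absence runs shorter than 50 frames (false negatives); and enlargement
by 40 px on every side (≈ 2 degrees under the scene camera), clamped to the
frame. On synthetic tracks whose dropouts and spurious blips respect those
bounds, post-processing restores the exact ground-truth presence runs.

Annotation tests each gaze position against the enlarged boxes with
priority **face > task > person**: faces are nested in persons and are the
semantically specific target; the enlarged task sheet may graze a person
box, and the task is the more specific label there too. By default the AOI
boxes are interpolated to the native 50-Hz gaze timestamps. The opposite
direction — gaze resampled to the 25-Hz frame grid — is available
(`direction = "gaze_to_frames"`), but it quantises AOI entry times to 40 ms,
which is too coarse for the 20-ms latency tolerances of the turn-aligned
metrics; that is why the gaze-grid direction is the default here.

Pupil baselines are computed per face, as the mean diameter during the
longest fixation on that face ending before noise onset; faces without a
qualifying fixation get a missing baseline, a warning, and no pupil
features. Baseline-subtracted dilation is defined only on samples gazing at
a face with a baseline.

## Turn-aligned metrics

States: talking = own turns; listening = others' turns minus own talking
(simultaneous speech counts as talking); everything else is unlabeled.
Transitions are consecutive turns (by onset) of different talkers; at each
transition the next turn's talker is the *next talker*, the third
participant the *remaining listener*, and a listener's role at the
listening offset is *self-turn* if they take the next turn, else
*other-turn*. Same-talker consecutive turns (possible when an interruption
blocked merging) produce no role-split event.

* **Dwell** is the percentage of a state's non-missing samples per AOI
  class; faces are reported separately and also folded into "people"
  (the three-AOI presentation: task, interlocutors, faces).
* **Onset latency** is the signed time, relative to a turn onset, of the
  first sample within ±4 s labelled with the new talker's person-or-face
  AOI (for talking onsets: any interlocutor). Sample-based latency is the
  default; the first/last-*fixation* probabilities use fixations, labelled
  by the majority AOI of their samples, as their definitions require.
* **Offset latency** is the signed time, relative to a turn offset, at
  which gaze last leaves the target's AOI within the window. The
  fixation-end-anchored variant is also computed (`latency_fix`), but the
  sample-based definition is the default because fixation ends carry the
  ~2-sample I-DT/smoothing bias described above, while AOI exit times do
  not.
* **Dwell difference** at offsets: dwell%(current talker) − dwell%(other
  listener) for listeners, and dwell toward next talker vs remaining
  listener (plus their difference) for talkers.
* **Movement/pupil features**: saccade rate (saccade onsets in state /
  state duration), mean fixation duration (fixations with midpoint in
  state), mean and max baseline-subtracted dilation on face samples.

Medians and IQRs are computed per trial; cross-trial aggregation is left to
the exported tidy table, whose rows (group, participant, trial, condition,
state, feature, value) mirror the factors of the downstream mixed model.

## The synthetic-trial generator

The generator is first-class, tested code; its defaults are the study
conditions.

**Conversation plans.** Alternating-talker sequences with gamma-distributed
turn durations (mean 3 s, sd 1.5 s, floored at 1.5 s so every true turn
survives the 1-s filter even with boundary error), inter-turn gaps from a
truncated normal with mean 250 ms — the canonical conversational gap — and
optional onset overlap. The source study reports no empirical turn/gap
distributions for its own data, so these are explicitly configurable
placeholders. Trials begin with a 5-s lead-in before noise onset, used by
the pupil-baseline machinery.

**Audio.** Speech is amplitude-modulated speech-shaped noise: white noise
shaped to a band-limited (100–8000 Hz), tilted long-term spectrum, with a
4-Hz raised-cosine syllabic envelope of depth 0.8 — enough level contrast to
make the frame-RMS distribution bimodal without shipping recordings. All
streams (3 talkers, 8 babble talkers) derive from one shaped carrier by
large circular shifts, which keeps them mutually uncorrelated at the lags
that matter while costing one spectral shaping per trial. Channels mix the
direct path (0 dB), crosstalk attenuated 10 dB and delayed by the 1.5-m
seat distance (4.37 ms at 343 m/s), the mouth-to-in-ear path (1.0 ms, −3
dB; see the in-ear rule discussion), and diffuse babble: the 8-stream
babble mix reaches each channel through its own circular shift, a cheap
diffuse-field decorrelation. Levels are dB re full scale and describe the
*close-mouth channel*, not the room: speech sits at −20 dB FS with babble
at −50 dB FS (30 dB below speech) in quiet and −32 dB FS (12 dB below
speech) in noise. The room SPL contrast between conditions is 30 dB
(48 vs 78 dB), but a boom microphone a few centimetres from the mouth
compresses that contrast — if the full 30 dB were applied at the channel,
the noise condition would sit at 0-dB SNR on the close mic and no energy
VAD (including the real study's) could have segmented it. Reverberation,
HRTFs and real speech synthesis are non-goals.

**Gaze.** A target schedule couples gaze to the plan: listeners reach the
new talker's face at onset + 0.4 s and leave at offset − 0.3 s; talkers go
to the task sheet at onset + 0.3 s and, in the final 4 s of their turn,
split time between task (30%), the remaining listener (20%) and the next
talker (50%), ending the next-talker fixation just after their offset.
Before noise onset the participant alternates 2-s fixations between the two
faces (baseline material). Schedules are realised as fixation–saccade
processes (gamma durations, mean 1.2 s listening / 0.45 s talking, floor
150 ms; 40-ms transits; consecutive centroids at least 2.5 degrees apart so
scripted fixations are separable at the 1.5-degree I-DT threshold), with
0.1-degree angular measurement noise, Poisson blinks (0.08 /s, 100–180 ms —
within the 200-ms interpolation bridge, so scripted fixation counts remain
recoverable; longer blinks are legal input and exercised in unit tests),
and transits placed so that injected arrival and departure times are exact
at the sample level. The pupil is 4.0 mm plus a +0.15-mm offset after noise
onset in the noise condition, AR(1) noise (phi 0.8, innovation 0.008 mm) and
sparse ±1-mm single-sample artefacts. AOI tracks get 2-px jitter, interior
dropout runs of 5–45 frames and spurious sub-4-frame blips (displaced, half
of them under the size floor). Ground truth — turns, events, per-sample AOI
occupancy (computed from noiseless positions against the clean enlarged
boxes), injected latencies, dwell fractions, the pupil offset — is exported
with every trial.

**What the simulator does not emulate.** Real speech spectra and prosody,
room acoustics, head movement (gaze angles are head-fixed), smooth pursuit
and vergence, AOI detector biases that correlate with pose, and pupil
light/gaze-position artefacts. Passing recovery tests therefore shows that
the *measurement machinery* is correct under the stated signal model, not
that the thresholds are optimal for any particular hardware.

## Recovery experiments and their design

Latency-recovery experiments isolate the injected latency as the only
determinant of talker-directed gaze: the script's talk-window fractions are
set to task-only (otherwise the scripted anticipatory gaze at the
observer's own talking offsets — a real behavior the default script
emulates — legitimately produces early first-entry times), and plans use
6-s turns so the ±4-s windows cannot reach the tail of the previous
same-talker turn. They feed ground-truth turns to the metrics stage: they
are parameter-recovery checks of the gaze machinery, and VAD boundary error
(±200 ms tolerance) would otherwise dominate the 20-ms latency tolerance.
The end-to-end path with detected turns is exercised separately. Dwell
recovery is asserted on the people/task/none classes: the face/person split
is sensitive to transition samples crossing the person box between face and
task sheet — a geometric fact of nested AOIs, visible in the ground truth
as well. The saccade-rate recovery experiment scripts fixations with a
0.3-s floor — processes containing sub-250-ms fixations are biased low by
roughly 5–8% because those fixations are not separable at this sampling
rate (see above) — and pools saccade counts over trials, since a rate is a
ratio estimate and a single ~30-s talking state holds only ~50 events.

Problem sizes used by the test-suite and the acceptance script: ten 60-s
rendered trials for turn recovery; 1000 constructed cases for the crosstalk
rules; 1000 random ≤ 50-sample traces for I-DT equivalence; six 120-s gaze
simulations per injected latency (≥ 50 events each); three 120-s
simulations per condition for dwell/rate/pupil recovery; 100 degraded AOI
tracks; 10-s audio pairs at 10-dB SNR for clock alignment.

## Numerical choices and degenerate inputs

* Frame grid: trailing partial frames are dropped (undefined RMS support).
* Cross-correlation: FFT-based, unnormalised for the peak search,
  normalised by signal energies for the reported peak value; lag searched
  over ±300 samples; frame-level tests use a ±100-ms context, the
  segment-level in-ear test up to ±0.5 s around the segment centre.
* Otsu: 64 bins spanning the observed range; the threshold is the bin edge
  maximising between-class variance.
* Interpolation limits translate to sample counts as *strictly shorter
  than* the stated duration (gaps < 200 ms at 50 Hz = at most 9 samples;
  absences < 50 frames = at most 49).
* Moving medians use shrinking windows at the edges and ignore NAs inside
  the window; even window requests are rounded up to odd.
* Empty inputs: empty masks give empty utterance lists; silent channels
  take the threshold fallback; all-missing pupil traces warn and return an
  empty trace; a zero-span recording is rejected.
* Determinism: every stochastic stage consumes one seed; `run_trial`
  derives per-stage seeds from the trial seed, and repeated runs are
  bit-identical.

## Known limitations

Fixation boundaries at 50 Hz carry the ~2-sample smoothing/I-DT bias
discussed above. The VAD threshold is per-conversation and static; slow
level drift within a conversation is not tracked. The clock model for
audio/eye-tracker alignment is a constant offset without drift. The in-ear
delay rule's physical intent remains ambiguous and is configurable rather
than resolved. Overlapping speech is handled only by the stated precedence
rules; overlap-resolution beyond them, ASR, and backchannel content
classification are out of scope.
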