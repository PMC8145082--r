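---
title: "Coding screen gaze and dialogue in consultations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding screen gaze and dialogue in consultations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screentalk)
```

## The coding problem

Studying how clinicians divide attention between the patient and the
electronic record traditionally requires manual video coding — expensive,
obtrusive, and slow. `screentalk` automates the lowest layer of that coding:
for every 0.5 seconds of a consultation recorded by the computer's own
camera and microphone, it decides whether the doctor is gazing at the screen
and whether a conversation is audible, and combines the two bits into four
interaction classes (`SG+D`, `D`, `SG`, `Other`). The 0.5-second window is
the atomic coding unit throughout: both detectors, the fusion, the
ground-truth conversion and every evaluation statistic live on the same
half-open grid `[0.5k, 0.5(k+1))`.

## The screen-gaze rule

The rule consumes five facial keypoints per frame (nose, both eyes, both
ears) with detection confidences, as emitted by common pose estimators. A
frame is *screen gaze* iff

1. both ears are estimated (confidence strictly above
   `presence_threshold`, default 0), and
2. the nose is centred between the eyes:
   `|x_nose − (x_LE + x_RE)/2| ≤ tolerance_factor · |x_LE − x_RE|`,
   with `tolerance_factor = 0.5` by default.

Assumptions: the camera sits on or near the screen, so a frontal head pose
is a usable proxy for screen gaze; the doctor is the person closest to the
camera (see `select_primary_person()`, which picks the largest mean
inter-eye distance and breaks ties to the lower person id); head *yaw* is
the motion that distinguishes screen from patient. That last assumption
motivates the default axis convention: offsets and distances are measured on
the x axis only. A Euclidean variant (`axis = "euclidean"`) is available for
cameras mounted well above or below the gaze line, where pitch leaks into
the vertical coordinate.

Three boundary conventions are deliberate and tested:

* **Inclusive tolerance.** An offset exactly equal to the tolerance counts
  as screen gaze (`≤`, not `<`) — a "tolerance" includes its boundary.
* **Presence.** "Estimated" means confidence strictly above the threshold;
  the default threshold 0 accepts any positive confidence because backends
  scale confidences differently. It is configuration, not code.
* **Missing frames.** Frames where the person is undetected are labelled
  no-screen-gaze rather than dropped, so the video grid never drifts
  against the audio grid.

## Voice activity and the dialogue series

Audio (mono PCM, any sample rate; 16-bit or float WAV) is cut into
consecutive `segment_ms` = 5-ms segments; a trailing remainder shorter than
one segment is dropped. Each segment receives a binary voice decision. The
package ships a reference energy detector so the pipeline has no external
runtime dependency: a segment is voiced iff its level in dBFS strictly
exceeds an adaptive noise floor plus an activation margin `delta_db`. The
floor is the 10th percentile of per-segment RMS levels (R's default
`quantile` type 7; digital silence is clamped at −96 dBFS), which is robust
as long as roughly a tenth of the recording is non-speech — true of any
consultation with typing or examination phases. The detector's
`aggressiveness` ordinal (0–3) maps onto the margin as 3/6/9/12 dB; the
default is the strictest setting (12 dB), which filters non-speech hardest.
The mapping is stated, arbitrary, and overridable via `delta_db`; an
external per-segment VAD can be plugged in as a function and inherits all
windowing behaviour.

The reference detector is amplitude-covariant (scaling audio and floor
together leaves decisions unchanged) and has no hangover smoothing: a
silence long enough to dominate a window is coded as absent dialogue. That
is a feature for some research questions (hesitation, silence detection) and
a known error mode for others; see the turn-gap analysis below.

## Windowing: one vote rule everywhere

Frame labels (at `fps`) and segment decisions (at `1000/segment_ms` per
second) are aggregated identically: each full window takes the majority
label of its frames; ties resolve to the *previous window's* resolved label
(temporal continuity), and to 0 at the start of a stream; a trailing partial
window is kept iff it contains at least half a window of frames. Using one
rule for both modalities guarantees the two series have equal length on any
common duration representable in whole frames, which the fusion then relies
on. Fusion itself is a bijection per window between the (gaze, voice) pair
and the four classes; on unequal lengths it truncates to the shorter series
with a warning (tails of real recordings differ), while *evaluation*
functions refuse mismatched lengths outright — scoring must never silently
align.

## Evaluation machinery

`confusion_matrix()` uses the fixed class order (`SG+D`, `D`, `SG`,
`Other`), rows = truth. `classification_report()` computes per-class
precision, recall, F1 and support, overall accuracy, and support-weighted
scores; metrics with zero denominators are defined as 0 so that sparse
classes never produce NaNs. Weighted recall equals accuracy identically (a
tested invariant, to 12 decimals). Reported values round half away from
zero — metrics to 2 decimals, percentages to 1 — so that printed tables are
reproducible from counts.

Per-video accuracy comparisons use the pooled-variance two-sample *t* test
(df = n₁ + n₂ − 2, e.g. 18 when two raters each code 10 videos); Welch is
available behind `pooled = FALSE`. Zero-pooled-variance inputs are handled
explicitly: equal means give t = 0, p = 1; unequal means give an infinite t
flagged `degenerate`.

**Transitions.** A transition is any window where the class changes.
`qualifying_transitions()` keeps those flanked by at least 1.5 s (3 windows)
of a single class on both sides, boundary inclusive. A misclassified window
is *transition-attributable* iff it lies within `radius` = 2 windows
(0.5–1 s) of a qualifying boundary **and** its predicted label equals the
truth on the other side of that boundary — i.e. it marks a real transition
early or late rather than inventing a class. The opposite-side condition
and the per-window (rather than per-transition) counting are this package's
operationalization of "timing error"; the radius is a parameter precisely
because other operationalizations are defensible, and the attribution count
is bounded by 4 × (qualifying transitions), which the tests assert.

## The consultation simulator

No clinical recordings ship with the package; the simulator exists so every
stage is testable against a known script.

* **Head geometry.** Eyes at azimuths ±30° on a unit circle, nose
  protruding at radius 1.8, ears at ±90°; image x = radius · sin(azimuth +
  yaw) · 200 px. The far ear is occluded beyond 30° of yaw. These constants
  are invented stand-ins — the validation surface is *self-consistency*:
  under this projection the gaze rule flips analytically at
  θ\* = atan(r sin α / (r_n − r cos α)) ≈ 28.2°, and a fine yaw sweep
  through the projected frames must locate the same boundary (tested to
  within 1°, observed agreement ~0.01°, the sweep's step size).
* **Yaw trajectories.** Screen-facing segments draw yaw about 0° (sd 5°),
  away segments about 45° (semi-inclusive layout) or 90° (fully inclusive),
  sd 10°, split evenly between a per-segment mean and per-frame spread. The
  two layouts reproduce the expected direction of the layout effect: the
  fully inclusive margin to θ\* (≈62°) dwarfs the semi-inclusive one
  (≈17°), so fully inclusive accuracy is never worse on matched scripts — a
  property asserted on the simulator, which says nothing about clinical
  data.
* **Speech.** Dialogue segments contain speech bursts (lognormal, mean
  2.5 s, sd 1 s, clamped at 0.6 s minimum) at −20 dBFS over a −60 dBFS
  microphone floor, separated by turn-taking gaps drawn from 0.2–0.4 s;
  everything else is floor noise. Scripts sampled by `sample_script()` live
  on the 0.5-s grid (transitions fall on window boundaries) with segment
  durations clamped to 2–20 s, mimicking coder-style annotations.
* **Degradations.** Gaussian pixel jitter (default 0.5 px) and per-keypoint
  dropout (default 0) are applied by `perturb_stream()`, seeded and
  reproducible.

What passing tests show — and what they do not. The recovery tests show the
*pipeline* is correct: rule, windowing, fusion and scoring compose without
drift, and under low noise the scripted timeline is recovered exactly away
from transitions. They do not validate the gaze rule against real heads
(the geometry is synthetic), nor the energy detector against real speech
(no phonetics, no reverberation, no overlapping speakers).

### The low-noise operating point, derived

Two window-arithmetic facts define what "low noise" must mean for an exact
recovery claim:

1. **Turn gaps.** A silence of length g inside one 0.5-s window flips that
   window to non-dialogue iff g ≥ 0.25 s. Gaps up to 0.4 s therefore
   *expectably* flip occasional mid-dialogue windows — that is the D→Other
   error mode the simulator is supposed to reproduce (and a dedicated test
   verifies that lengthening gaps beyond 0.5 s strictly increases it). The
   low-noise scenario draws gaps from 0.20–0.24 s, provably below the flip
   threshold.
2. **Away-yaw margin.** A semi-inclusive away segment has a 16.8° margin to
   θ\*. With the default sd 10° (5° segment-level + 5° frame-level), a
   ~3σ segment draw puts the whole segment near the boundary and flips
   windows mid-segment with probability ≈10⁻³ per segment — rare but
   visible across thousands of segments. The low-noise scenario halves the
   spread (sd 5°), pushing the flip probability below 10⁻⁸.

Under that operating point, ten 3-minute sessions (five per layout) are
recovered at overall accuracy 1.0 at the tested seeds — and ≥ 0.95 is
asserted separately under the *default* noise, where gap flips and boundary
windows legitimately cost a few percent. Transition-adjacent windows
(within 1 s of a scripted boundary) are excluded from the exactness claim
because window discretisation makes a one-window shift at a boundary an
artefact of phase, not an error of substance.

## Problem sizes and runtime choices

The property suite runs randomized streams of ≤ 1000 windows against
brute-force oracles; the recovery tests simulate ten 3-minute sessions at
8 kHz audio (the acceptance script uses 16 kHz), sizes chosen so the full
suite completes in well under a minute per file while every window-level
code path (ties, partials, boundaries, dropouts) is exercised. All
simulation is seeded; identical seeds give bit-identical sessions.

## Known limitations

* Head yaw is short-term attention; torso and lower-body orientation, which
  communicate longer-term engagement, are out of scope.
* Exclusive layouts (screen behind the doctor) defeat the frontal-pose
  proxy entirely.
* The dialogue bit detects voice activity, not speakers: a doctor dictating
  notes while facing the screen codes as `SG+D`. Diarization is explicitly
  not attempted.
* The interval→window conversion assigns each window by majority overlap
  (ties to the earlier interval); annotations finer than 0.25 s within a
  window are unrepresentable on the grid by construction.
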