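# screentalk

Behavioural coding of doctor–patient–computer interactions from a
consultation recording made with the computer's own camera and microphone —
no extra sensors in the clinic. `screentalk` classifies every 0.5 seconds of
a consultation into one of four interaction classes:

| screen gaze | dialogue | class  |
|-------------|----------|--------|
| yes         | yes      | `SG+D` |
| no          | yes      | `D`    |
| yes         | no       | `SG`   |
| no          | no       | `Other`|

Two simple, fully inspectable detectors feed the fusion:

* **Screen gaze.** From five facial keypoints per frame (nose, eyes, ears, as
  produced by a pose estimator), a frame is *screen gaze* iff both ears are
  estimated and the nose is centred between the eyes with a tolerance of half
  the inter-eye distance:
  `|x_nose − (x_leftEye + x_rightEye)/2| ≤ ½ |x_leftEye − x_rightEye|`.
  A head turned away from the camera (and hence the screen) fails on either
  the occluded far ear or the nose offset. Frame labels are majority-voted
  onto 0.5-second windows.
* **Dialogue.** Audio is cut into 5-ms segments; each gets a binary voice
  decision (a self-contained energy detector against an adaptive noise floor,
  or any external per-segment VAD plugged in as a function), and segment
  decisions are majority-voted onto the same 0.5-second grid.

On top sit the evaluation tools used to validate such a coder against human
annotations — confusion matrices, per-class and support-weighted
precision/recall/F1, pooled two-sample *t* tests on per-video accuracies,
transition frequency tables, and an analysis that separates substantive
errors from 0.5–1-s early/late markings of real transitions — plus a
synthetic consultation simulator (scripted interaction states, a head-yaw
geometry model with an analytic rule boundary, speech bursts with
turn-taking gaps) so the entire pipeline can be exercised and tested without
clinical video.

## Worked example

Simulate a 100-second fully inclusive consultation, classify it end to end,
and score it against its own ground truth:

```r
library(screentalk)

scr <- scenario_script(
  states    = c("SG+D", "D", "SG", "D", "Other", "SG+D"),
  durations = c(20, 25, 10, 25, 5, 15),
  layout = "fully-inclusive", seed = 11)
ses  <- generate_session(scr)          # keypoints + 16 kHz audio + truth
pred <- classify_session(ses)          # gaze rule + VAD + fusion

classification_report(confusion_matrix(ses$truth, pred))
#>  class precision recall   f1 support
#>   SG+D      1.00   0.89 0.94      70
#>      D      1.00   0.89 0.94     100
#>     SG      0.71   1.00 0.83      20
#>  Other      0.48   1.00 0.65      10
#> accuracy 0.91 | weighted P 0.95 R 0.90 F1 0.92

err <- transition_error_analysis(ses$truth, pred)
#> errors: 19, transition-attributable: 1 (5.3%)
```

The 200 windows are recovered at 0.91 accuracy under the generator's default
noise. The residual confusions are the two modes one expects from the
method: windows adjacent to a scripted transition marked one window early or
late (the transition-attributable error above), and dialogue windows whose
0.5 seconds happen to be dominated by a turn-taking gap, which the VAD
correctly hears as silence and the fusion therefore codes `Other` — the
reason `Other` precision is low while its recall is perfect. Tightening the
gap length below half a window (`speech_model_config(gap_range =
c(0.20, 0.24))`) removes the second mode entirely and recovery becomes exact
away from transitions.

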