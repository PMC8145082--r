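Package: screentalk
Title: Screen-Gaze and Dialogue Coding of Doctor-Patient-Computer Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unobtrusive behavioural coding of clinical consultations recorded
    with the computer's own camera and microphone. A geometric head-pose rule
    over five facial keypoints (nose, eyes, ears) classifies each video frame
    as screen gaze or not; an energy-based voice-activity detector classifies
    short audio segments as speech or silence; both are majority-voted onto a
    0.5-second window grid and fused into four interaction classes (screen
    gaze + dialogue, dialogue, screen gaze, other). Includes evaluation
    machinery (confusion matrices, support-weighted precision/recall/F1,
    pooled t tests, transition detection and transition-timing-error
    attribution) and a synthetic consultation simulator (head-yaw geometry,
    speech bursts with turn-taking gaps, keypoint jitter and dropout) so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
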