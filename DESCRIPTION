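Package: gazeloop
Title: Closed-Loop Gaze-Contingent Joint-Attention Games, Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, testable engine for avatar-mediated response-to-joint-attention
    (RJA) training games driven by screen gaze. Provides real-time region-of-interest
    (ROI) hit-testing and dwell-based gaze-event detection, the deterministic finite
    state machines of a bubble-popping assessment game and a tangram-puzzle practice
    game, a rule-based adaptive-difficulty controller and a least-to-most (LTM)
    assistive prompting module, a parameterized synthetic gaze-stream participant
    simulator for end-to-end closed-loop testing, offline two-threshold dispersion
    fixation detection with ROI assignment, and the session metrics, speed-group
    scoring and pooled-SD effect sizes used to evaluate such interventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
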