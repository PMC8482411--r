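---
title: "Models and design decisions in gazeloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in gazeloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeloop)
```

`gazeloop` is a headless implementation of a gaze-contingent
response-to-joint-attention (RJA) training loop: an avatar establishes eye
contact, prompts toward an object with its gaze, and the game reacts to
where the player actually looks. This vignette documents the models the
package implements, the parameters that matter, and the choices made where
the design was genuinely open.

## The gaze runtime

Gaze arrives as timestamped samples `(t, x, y, valid)` at the 50–60 Hz rate
typical of consumer remote trackers; `valid = FALSE` marks blinks and track
loss. Screen geometry uses the desktop convention: origin top-left,
y increasing downward, all rectangles half-open `[x0, x1) × [y0, y1)` so
adjacent regions tile without double hits. Scenes contain exactly one
active *avatar-eye* region, passive facial features (forehead, both ears,
nose, mouth), and active game-object regions. When rectangles overlap, the
first declared wins, and `roi_set()` always promotes the avatar-eye region
to the front: a gaze landing on an eye/feature overlap should count as eye
contact.

Dwell is accumulated per ROI by timestamp differences, never sample counts,
so streams at different rates behave alike: entering an ROI starts an
episode at zero, each continuing sample adds the elapsed interval, and
leaving (or switching ROI) resets. One fixation trigger fires per episode
the first time dwell reaches **200 ms**, a conventional minimum human
fixation duration. The comparison is `>=`: at 50–60 Hz a strict and
non-strict comparison are observationally indistinguishable (no sample
lands exactly on the threshold except by construction), and `>=` makes
boundary behaviour deterministic in tests. Passive regions accumulate dwell
but never trigger game events; they exist for offline analysis.

Blinks shorter than the **gap tolerance (75 ms, configurable)** do not
reset a running dwell, because consumer trackers drop several samples per
blink and a blink should not cancel an otherwise steady gaze; the blink
interval itself contributes no dwell time. Real deployments may prefer
100–150 ms; 75 ms is deliberately conservative.

Two clocks run alongside: a **phase clock** (reset whenever the game phase
(re)starts) and an **interaction clock** (reset by any fixation trigger on
an active ROI). At 30 s of an unanswered share phase the engine cues the
player — a bell in both games, plus highlighting of the avatar's eye region
in the tangram game; the cue fires once per phase (whether it should repeat
is left open by the underlying design; firing once keeps the semantics
unambiguous, and the 120 s rule bounds the phase anyway). At 30 s of an
unanswered follow phase a follow timeout fires. At 120 s of the interaction
clock the session terminates. "Interaction" is defined here as *any
registered fixation trigger on an active region* — a looser reading than
strict eye contact, chosen so that a player actively but imperfectly
engaging with the objects is not cut off.

## The two game machines

Both games are deterministic finite state machines. The bubble game
(states: Initialize, Avatar Prompt, Bubble Pop; final state Initialize)
issues **50 prompts** over **8 bubbles**; every trial requires a fresh gaze
share before the prompt, a correct follow pops the bubble (one point) and
schedules its respawn **5 s** later, and a follow timeout simply moves on —
no assistance, no adaptation, prompt level pinned at 2, speed rising
deterministically `v = 2 + 2(k−1)` ups on prompt `k`. With 50 prompts over
8 bubbles targets necessarily repeat; the target is drawn uniformly from
the bubbles present at that instant (a bubble waiting to respawn is out of
the pool). Whether a timed-out trial requires a fresh share before the next
prompt is not fixed by the design; `gazeloop` requires it, keeping every
trial's structure identical.

The tangram game (states: Initialize, Play Avatar, Show Puzzle Color,
Enable Puzzle Movement) prompts one of **7 grey pieces**; a correct follow
restores the piece's colour and enables movement, and a discrete
move-to-target input (standing in for mouse drag physics) completes the
trial. Pieces never repeat: every trial ends with its piece placed, by the
player or by the engine.

### Adaptation and assistance (tangram only)

The difficulty controller starts at the level given by the game-number
schedule (games 1–3: head + full eye movement; 4–6: full eye movement only;
7–9: minimal 40 %-range eye movement) and 2 ups. Correct selections add
2 ups each and, after three in a row, raise the level (capped at 3). Wrong
attempts leave speed unchanged until three accumulate, which lowers speed
by 2 ups; a *further* three lower the level (floored at 1). The two-stage
wrong rule means a level decrease is always preceded, within the same wrong
run, by a speed reduction. Streak counters clear after any change they
trigger, and any correct disarms the staged rule. The speed floor is 2 ups
(the starting speed; no explicit minimum exists in the underlying design).
The controller is fed one `"correct"` per completed piece and one `"wrong"`
per failed follow attempt (each follow timeout), the closest reading of
"three consecutive wrong attempts" for a game in which a trial only ends in
placement.

Failed follows also walk the least-to-most ladder: attempt 1 highlights the
avatar's eye region with a sound cue and returns the engine to the share
phase (that row's stated purpose is re-establishing eye contact — and this
routing also keeps a re-sharing participant's interaction clock alive
mid-ladder); attempts 2–3 repeat the prompt at reduced speed (halved,
floored — "lower speed" comes with no number attached) with highlighting
and in-place rotation of the object at attempt 3; beyond 3 the engine moves
the piece itself, the trial ends `auto_assisted`, and no point is scored
("points accumulated" is defined in this package as pieces placed without
auto-assistance).

## The synthetic participant

The simulator exists so the whole loop can be exercised end to end: it
generates gaze sample by sample and pushes every sample through the real
runtime and engine — the session log is engine output, never synthesized
directly. A profile specifies:

- `p_share` — probability of sharing gaze within a share window, with a
  log-normal latency (median/σ); after the 30 s cue an undecided
  participant re-decides once, modelling the cue drawing attention;
- a logistic follow model `p_follow(v, L) = plogis(a − b·v − c·(L−1))` with
  a log-normal response latency;
- fixation jitter (Gaussian, SD in px), 30–80 ms linear saccades between
  targets, and Poisson blinks with log-normal durations;
- distractor behaviour when not sharing/following: dwells of 0.8–2.5 s
  drawn (by default exclusively) over the five passive facial features,
  emulating players who search the face for non-verbal cues; a mixture
  weight can divert some dwells to wrong game objects instead.

Latencies are log-normal because human reaction times are strictly
positive and right-skewed. Saccade kinematics are deliberately minimal —
linear interpolation is all the ROI logic can see. What the generator does
*not* emulate: smooth pursuit, head-pose error, calibration drift,
within-session learning (pre→post improvement is expressed by changing
profile parameters between sessions, an explicit experimenter action), and
anticipatory gaze. Passing tests therefore demonstrate the correctness of
the loop's *rules*, not ecological validity of the streams.

Cohort families (`td_like`, `asd_like_pre`, `asd_like_post`, `ideal`) are
this package's own calibration — higher follow intercepts and shallower
speed slopes for the `td_like` family, the converse pre-intervention — and
individual profiles scatter around the family means on natural scales
(logit for probabilities, log for latencies). They produce the qualitative
signatures of interest (declining speed-group scores, positive pre→post
effect sizes), not any published participant's numbers.

For speed, the per-sample loop inlines the same dwell/timeout arithmetic
exposed by `update_dwell()` / `check_timeouts()`; a property test replays
recorded streams through the exported functional API and requires the
engine log to match event for event.

## Offline fixation detection

The analysis layer re-detects fixations from logged streams with a
two-threshold sequential dispersion method: a sample joins the running
cluster while its distance to the running centroid (incremental mean) is at
most `t1`; on exit the cluster closes, members farther than `t2` from the
closed centroid are removed and the centroid recomputed, and clusters
shorter than 200 ms are dropped. Defaults: `t1` = 1° of visual angle
converted through the screen geometry (`px = tan θ · distance · px/cm`,
60 cm viewing distance by default, ≈ 38 px); `t2` = 3 × SD of
member-to-centroid distances (the underlying method derives `t2` from the
cluster's standard deviation without fixing the multiplier; 3σ is the
conventional outlier cut, and a fixed pixel value is available). Removed
outliers are discarded entirely rather than seeding new clusters — they are
isolated flicks by construction. Membership against the *running* rather
than first-point centroid is likewise a documented choice; the brute-force
reference in the test suite pins the exact semantics.

Fixations are assigned to ROIs by centroid hit-test; the eye/other split
reports `eye/(eye+other)` and its complement, undefined (NA) when no face
fixation exists.

## Metrics and effect sizes

Per session: score (= correct trials, always equal to the count in the
trial records); time to complete (first prompt to last logged event,
seconds); mean response time over correct trials only (prompt to correct
fixation trigger; timeouts excluded and counted separately; trials that
received assistance are excluded from the headline mean by default, with a
switch to include them); and, for 50-prompt bubble sessions, the five
speed-group scores — consecutive blocks of 10 prompts, each spanning a
contiguous 20-ups speed band, 10 points maximum per group, always summing
to the total score. Grouping by consecutive prompts is the only partition
consistent with a 2-ups-per-prompt ramp; a "10 ups per cluster" reading
would need ten groups, an arithmetic inconsistency in the source design
that the package resolves by blocks of ten prompts.

Cohort summaries report mean (SD) per arm × timepoint and the absolute
standardized difference
`|d| = |m₁ − m₂| / √((s₁² + s₂²)/2)`.
The root-mean-square pooling is the form that reproduces the published
worked examples from their printed summaries (inferred, not stated, by the
source); it is symmetric and scale-invariant, and both properties are
tested. Published p-values from paired tests on unreleased raw data are not
reproducible from summaries; `t_stat_from_summary()` is provided as a
descriptive utility only.

## Problem sizes and numerical choices

All timestamps are integer milliseconds from session start, avoiding float
drift in dwell accounting. All randomness flows from a single `set.seed()`
per simulated session; identical (profile, config, seed) triples reproduce
streams and logs byte for byte.

The test suite verifies the dwell detector against an O(n²) from-scratch
reference on randomized streams, the fixation detector against a
brute-force sequential-clustering reference on 100 randomized streams, the
adaptation controller against a rule-transcription oracle over 10 000
random outcomes, and parameter recovery on 200 simulated 50-prompt bubble
sessions: per-speed-group follow rates must lie within family-wise 95 %
binomial bounds of the generating logistic (the family-wise reading — five
bins jointly — is used because five simultaneous per-bin tests at 95 %
would be miscalibrated), and mean group-5 scores must fall strictly below
group-1 scores, with a steeper speed slope depressing them further. These
sizes keep the full suite within a few minutes on one CPU while leaving
each check statistically meaningful.

## Known limitations

- The engine models piece movement as a single discrete input; drag paths,
  partial moves and mouse slips are out of scope.
- The dwell detector is dispersion/dwell-based by design; no velocity
  (I-VT) classification, no smooth-pursuit handling, no binocular
  disparity.
- The 40 % movement-range prompt level and prompt speeds affect only the
  follow model's success probability — there is no rendering, so prompt
  kinematics are not themselves simulated.
- Family profiles are plausible calibrations, not fitted to any cohort;
  conclusions about real populations require real data.
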