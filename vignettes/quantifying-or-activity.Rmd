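---
title: "Quantifying operating-room staff activity and workload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying operating-room staff activity and workload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orpose)
library(dplyr)
```

`orpose` quantifies what intra-operative nurses and other staff do during
surgery from ceiling-camera pose detections, and relates that to perceived
workload and job satisfaction measured with an extended Surgery Task Load
Index. This vignette explains the models and rules the package implements,
the tunable parameters and their defaults, what the synthetic-data
generators emulate, and the numerical choices made where the design was
genuinely open.

## The activity model

The central observable is a per-frame binary state per person: *active at
the operating table*. A pose estimator supplies 17 COCO-style keypoints
(pixel coordinates + confidence) per person per frame; one camera view
carries three annotated zone polygons around the table. A person is active
in a frame when all of the following hold:

1. **both wrists** lie inside the wrist (table) zone,
2. **both shoulders** lie inside the shoulder zone,
3. the **head centroid** — the mean of whichever of nose, eyes and ears
   are detected — lies inside the head zone, and
4. the upper body is not translating: the displacement of the shoulders
   and head over the preceding `window` frames does not exceed
   `displacement_threshold`.

Requirements 2 and 3 exist because of camera perspective: a wrist belonging
to someone merely reaching or walking past the table must not count as
table work, so the shoulder and head subsets must also sit in their own
annotated areas. Requirement 4 vetoes people walking through the zones.
Wrist motion deliberately never enters the veto (wrists are *expected* to
move while working) and leg keypoints never enter any rule (gowns and the
overhead viewpoint make them unreliable).

Frames where a required keypoint is missing, or where the displacement
cannot be computed, are labelled `undetermined` unless a definite rule
already fires: a failed zone test or an exceeded movement threshold yields
`inactive` even if the other test is unavailable.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `displacement_threshold` | 17.5 | px per window | movement veto; fires only when *strictly* exceeded |
| `window` | 5 | frames | displacement window, endpoint-to-endpoint |
| `min_confidence` | 0.3 | — | keypoint presence cut-off |
| `aggregate` | `"mean"` | — | how shoulder/head displacements combine |

Numerical choices that were genuinely open, and how they were settled:

* **Displacement aggregation.** "Movement of the shoulders and head" does
  not name an aggregator. The default is the *mean* of the three
  point-displacements (left shoulder, right shoulder, head centroid),
  which is robust to a single noisy point; `aggregate = "max"` is
  available for a stricter veto.
* **Endpoint-to-endpoint, not path length.** Displacement "over 5 frames"
  is read as a 5-frame offset. Summing frame-to-frame steps would
  double-count detector jitter and make the veto fire on stationary but
  noisy poses.
* **Strict inequality.** The veto uses "exceeded", so a displacement of
  exactly 17.5 px still counts as active. This matters only on a measure-
  zero boundary but makes the classifier deterministic there.
* **Zones instead of y-ordering.** "Shoulders above the wrists" and "head
  above the shoulders" are operationalised purely as membership in the
  annotated shoulder/head polygons. Under a ceiling camera, raw
  y-coordinate ordering is ill-defined; the three annotated areas are the
  operational definition.
* **Boundary-inclusive membership.** A point exactly on a zone edge is
  inside. This keeps the classifier deterministic at polygon edges.
* **Frame rate.** The camera frame rate is a recording property, not part
  of the method; the simulator default is 25 fps and everything that
  converts frames to seconds takes `fps` explicitly.

## Tracking

Detections are associated into identity-stable tracks with a two-stage,
confidence-split strategy in the BYTE style, adapted to pose data: the
similarity between a track's last observed pose and a detection is a
convex blend

\[ s = \lambda\,\mathrm{IoU}(b_1, b_2) + (1-\lambda)\,
   \exp\!\big(-\overline{d^2} / (2 s_0^2)\big), \]

with bounding boxes over the present keypoints, \(\overline{d^2}\) the
mean squared distance over keypoints present in both poses, and \(s_0\)
the mean box diagonal (an object-keypoint-similarity-style scale
normalisation). High-confidence detections are matched first by optimal
one-to-one assignment (Hungarian algorithm via `clue::solve_LSAP()`);
remaining tracks are then offered the low-confidence detections, which
recovers partly occluded people without letting weak detections create
tracks. Unmatched high-confidence detections spawn tentative tracks,
confirmed after `min_hits` matches; tracks unseen for `max_age` frames are
lost. There is no motion model: staff move slowly relative to the frame
rate, so the last observed pose represents the track. Ties in the
assignment are broken toward the lowest track id, then the lowest
detection index, so tracking is deterministic.

Defaults (`high_conf` 0.5, `low_conf` 0.1, `match_threshold` 0.3,
`max_age` 30, `min_hits` 3, `lambda` 0.5) follow the cited tracking
method's conventions; none of them is derived from clinical data, and all
are exposed in `tracker_params()`. The similarity blend is a declared
reconstruction — the original adaptation is not published as code — so
tests pin its *contract* (optimality of the per-frame assignment, identity
stability on separated staff) rather than any particular constant.

## Phase metrics

Procedures split into three clinical phases (patient entry to incision,
incision to closing — the "cutting phase" —, closing to patient exit).
Three phase-level percentages summarise a procedure:

* **activity** — summed active time of all persons relative to the *mean*
  duration of that phase across procedures of the same surgery type (so
  values exceed 100 % when several staff are simultaneously active);
  a per-procedure denominator is available via `mean_phase_durations`.
* **interaction** — the same combined occupancy relative to this
  procedure's own phase duration.
* **movement** — share of frames whose windowed displacement exceeds the
  activity threshold, averaged per person and then across persons
  (pooled person-frames available as `mode = "pooled"`).

**Handling of undetermined frames.** Each person's active fraction is
computed over *fully determined* frames only: the zone test must be
determined and the displacement available. Frames classified from partial
information — e.g. the veto firing while a wrist is missing — are also
excluded from the denominator. Under independent keypoint dropout the
probability that a frame is fully determined is the same whatever the
person is doing, so the estimated fraction is unbiased; including
partially determined frames would over-represent inactive states (walking
frames can be labelled inactive from the veto alone, while an active frame
needs all nine required keypoints plus both displacement endpoints).

Percentages are *not* invariant to uniform image rescaling: zone
membership is, but the displacement threshold is in pixels, so doubling
all coordinates doubles displacements against a fixed 17.5 px threshold.
This is asserted as a negative test in the suite; zone annotations and
thresholds belong to one calibrated camera view.

## The extended workload instrument

The Surgery Task Load Index scores six domains — mental demand, physical
demand, temporal demand, task complexity, situational stress,
distractions — on 0-20 scales. The package implements the extended form
with a seventh, exploratory domain, job satisfaction, on the same scale.
Each respondent scores every domain for each of three surgery types (open,
minimally invasive, robotic-assisted) and each of the three phases: 63
cells.

Analysis rules:

* **Complete cases only.** A respondent with any missing cell is excluded;
  no imputation (`surgtlx_complete()`).
* **Aggregations.** Phase-summed scores (0-60, per surgery type) feed the
  across-type comparison; type-summed scores feed the across-phase
  comparison. The overall workload per surgery type is the per-respondent
  mean of the six *original* domains' phase-summed scores, averaged over
  respondents — job satisfaction is excluded by construction, and tests
  assert that changing satisfaction cells cannot move it. This aggregation
  is a declared reading: with every cell equal to *c* it gives 3*c*, i.e.
  it lives on the 0-60 phase-sum scale.
* **Tests.** A Friedman rank test per domain (average ranks, the standard
  tie correction; the uncorrected classical statistic is reported
  alongside because statistical packages differ here), with Kendall's
  \(W = \chi^2_F / (n(k-1))\) as the effect size. An ANOVA-style
  partial-eta-squared is deliberately *not* reported: for a rank design
  its definition is ambiguous, and published magnitudes of that kind are
  not treated as reproducible targets. When the omnibus test is
  significant at `alpha` (default 0.05) the Nemenyi post-hoc locates the
  differing pairs from the studentized-range distribution on mean-rank
  differences with standard error \(\sqrt{k(k+1)/(6n)}\). No correction is
  applied across the seven domains, matching the instrument's customary
  reporting.

## Hospital schedule metrics

Per-procedure records carry planned and actual durations per phase, an
ASA-like risk class, an emergency flag and a staff count.
`schedule_deviation()` reports signed actual-minus-planned minutes per
phase and in total; `dark_time()` proxies time under dimmed lights by the
actual cutting-phase duration (dimming occurs primarily in phase 2), and
accepts a dedicated `dark_time_min` field when a dataset records it
directly; `summarize_schedule()` gives complete-case group means per
surgery type.

## What the synthetic generators emulate — and what they do not

Real recordings and questionnaires from clinical settings are not
distributable, so every stage is exercised on seeded synthetic data with
known ground truth.

**Scenes** (`simulate_scene()`): staff walk between a home position at the
image border and standing slots around a table carrying the three nested
default zones; during scheduled bouts the wrists reach into the table
zone, shoulders and head rest in their zones, and the upper body is
stationary. Walking speed is set so the windowed displacement clears the
threshold by a configurable margin (default 30 %), making veto tests
sharp. Persons arrive at their slot `window` frames before a bout, so on
noiseless input the classifier reproduces the schedule exactly beyond the
warm-up; the auto-generated schedules leave room for that travel.
Observation noise is isotropic Gaussian jitter plus independent
per-keypoint dropout. Not emulated: occlusion between people, correlated
detector failures, pose-estimation bias near image borders, perspective
distortion of body proportions, or more than one camera. Passing tests
therefore show that the *rules* are implemented correctly and are robust
to unstructured noise — not that any specific pose estimator is accurate
in a specific room.

**Questionnaires** (`simulate_surgtlx()`): each cell is normal with a
configurable mean/SD, clamped to 0-20. Clamping (rather than resampling)
keeps the generator monotone in the configured mean; near the scale ends
it biases cell means toward the centre, which recovery tests account for
by checking mid-scale cells. The reference calibration
(`surgtlx_reference_params()`) uses published phase-summed descriptives
divided by 3 for the four domains with published per-type statistics; the
remaining three domains get neutral values chosen once to preserve the
published ordering of overall workload (robotic-assisted highest). Real
respondents differ in ways the generator ignores: per-respondent response
styles (correlated cells), integer scoring, and skewed distributions.

**Schedules** (`simulate_schedule()`): surgery-type profiles chosen once
to mirror routine gynaecology practice — minimally invasive procedures
most frequent and shortest, open and robotic similar in length with the
robotic cutting phase longer, open patients at higher risk and often
finishing early, robotic procedures overrunning. All profiles are
arguments.

## Problem sizes used in the packaged checks

The test-suite and the acceptance script run, among other things: 100
random scenes of up to 5 persons and 200 frames against a brute-force
rule oracle; 20 noisy scenes for occupancy recovery; 50 tracker runs of
300 frames with 5 % dropout; 2000 null replicates for the Friedman
type-I rate at n = 19, k = 3; and 500 simulated questionnaire cohorts of
19 respondents for the direction-of-effect calibration. These sizes give
Monte-Carlo error well below the tolerances they are checked against
while keeping a full run in the minutes range on a single core.

## Known limitations

* The zone classifier needs one calibrated camera view; thresholds are in
  pixels of that view and do not transfer across views or resolutions.
* Identity maintenance has no appearance model, so staff who leave the
  field of view for longer than `max_age` frames return as new tracks.
* Binary table-activity is a coarse proxy for involvement; instrument
  handovers and other hand-level events are out of scope.
* The job-satisfaction domain is an exploratory addition to a validated
  six-domain instrument; its scores are analysed with the same machinery
  but should be interpreted as indicative.
* Friedman/Nemenyi tests assume exchangeable rows; the simulated
  questionnaire cells are independent within respondent, which real data
  will not be.

## A minimal end-to-end run

```{r pipeline}
sc <- simulate_scene(scene_config(
  n_staff = 2, phase_durations = c(10, 20, 10),
  jitter_sd = 1, dropout_rate = 0.02, seed = 42
))
tracks <- build_tracks(sc$detections)
activity <- classify_activity(tracks$poses, sc$zones)
phase_metrics(activity, sc$timeline)
```

```{r surgtlx}
responses <- simulate_surgtlx(19, surgtlx_reference_params(), seed = 42)
res <- surgtlx_analyze(responses)
tidy(res) %>% filter(domain %in% c("temporal", "satisfaction"))
```
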