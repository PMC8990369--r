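---
title: "Measuring children's television viewing from frame-level face and gaze observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring children's television viewing from frame-level face and gaze observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gazewatch)
library(dplyr)
```

## The measurement problem

Objective measurement of how long a child watches a television screen is
normally done by human coders watching recorded video and applying
duration codes (`watching`, `not_watching`, `out_of_frame`,
`cannot_tell`): one code persists until the behaviour changes. That gold
standard is accurate but too expensive for routine studies, which
otherwise fall back on parent report. A camera placed on top of the
screen, facing the viewers, allows an automated alternative with three
decisions per video frame:

1. **Face detection** — find candidate faces and keep those whose
   detector confidence clears a threshold chosen on an ROC
   (sensitivity against false positives per second of recording).
2. **Face verification** — decide which detected face, if any, is the
   *target child*, by correlating the face's identity embedding against a
   small enrollment gallery collected at the start of the study, with
   temporal smoothing along face tracks.
3. **Gaze dichotomization** — convert the verified child's gaze direction
   vector into a binary gaze-on-screen decision using angular limits
   that depend on where the face sits in the frame and where the
   television is in the room.

Summing the viewing frames and dividing by the frame rate yields the
child's total viewing time, reported in `minutes:seconds`. This package
implements that measurement logic, the calibration machinery around it
(ROC operating points, leave-one-family-out angular-limit fitting), the
agreement statistics used to evaluate it against duration-coded gold logs
(confusion-matrix metrics, PABAK, Cohen's kappa, intraclass
correlations, paired Wilcoxon tests), and a synthetic session simulator
that makes every stage testable without video data or trained networks.
The deep networks that would produce boxes, embeddings and gaze vectors
from real video are deliberately out of scope: they enter only through a
backend contract (any per-frame table of boxes, scores, embeddings and
gaze vectors can be fed to the pipeline).

## The synthetic session model

`simulate_session()` emulates a laboratory or in-home observation of a
parent–sibling–target triad. Its defaults are the package's reference
study conditions; every one of them is a `session_config()` field.

**Geometry.** The camera sits at the top-centre of the screen box; pixels
map to 3-D rays through a pinhole with focal length 600 px; people sit at
fixed depths (2, 2.2, 2.5 m) in separate horizontal slots of the frame
(which keeps face boxes disjoint so that identity tracks are
unambiguous), wander around a home position by a bounded random walk
(`walk_sd` = 1.5 px/frame, reflected at `walk_range` = 25 px), and an
optional `home_xy` fixes the seating across sessions of one family.

**Gaze convention.** Gaze vectors are unit 3-vectors in a camera-facing
frame: x right, y down, z pointing from the scene toward the
camera/display plane, so that a child looking straight at the camera has
gaze (0, 0, 1) and screen-directed gaze has small yaw/pitch
(`yaw = atan2(x, z)`, `pitch = atan2(-y, sqrt(x^2 + z^2))`). This keeps
the fitted angular windows away from the ±180° wrap-around that would
occur if z pointed into the scene.

**Behaviour.** The target child alternates `watching`/`not_watching` as a
two-state Markov process with per-second rates (defaults 0.02 and 0.011,
stationary watching fraction ≈ 0.36 and multi-minute bouts, matching
roughly one-third of a session spent watching), and leaves the room as a
Poisson process (`p_exit` = 0.002/s) with exponentially distributed
absences (mean 30 s) coded `out_of_frame`.

**Observations.** When watching, the emitted gaze is the exact
face-to-screen-centre direction perturbed by independent Gaussian
yaw/pitch noise (`gaze_noise_deg`, default 10°). When not watching, the
gaze points to a direction sampled uniformly outside an exclusion cone of
radius (screen angular half-extent + max(2·σ, 10°)) around the screen
direction: the screen-extent term stops "not watching" gaze from pointing
at the screen itself, and the 10° floor keeps the two classes separable
as σ → 0, so exact-recovery tests are well posed. Embeddings are drawn
around per-person identity centroids placed on the unit hypersphere with
45° pairwise separation and per-coordinate noise `embedding_noise_sd`
(default 0.016), then re-normalised. Spurious (non-face) detections
arrive at `fp_rate` = 0.053 per frame with confidence scores in
\[0.5, 0.95\] and random embeddings — at 15 frames/s this reproduces a
raw detector false-positive rate of ≈ 0.8/s, essentially all of which
the verification stage screens out because random embeddings are
uncorrelated with the gallery.

**Lighting.** `bright`, `dim` and `dark` multiply the detection miss
probability, the embedding noise and the gaze noise by 1, 2 and 4 and
subtract 0, 0.08 and 0.16 from detector confidence. The embedding noise
default was chosen so the three levels span the verifier's operating
range around the 0.93 match-score threshold: bright is essentially
error-free, dim straddles the threshold (impaired but functional), dark
falls below it — low light being the principal error source such systems
report. Note that track-majority smoothing largely *masks* the dim-light
degradation (it restores per-frame sensitivity towards 1), which is why
degradation analyses of the raw verifier should use a smoothing window of
1.

**Determinism.** Every stochastic component is drawn in a fixed order
with fixed draw counts, so two configurations differing only in lighting
or noise levels share their underlying draws; measurement noise is the
shared N(0,1) stream scaled by the noise parameter. This makes
degradation monotone per seed, not just in expectation, and keeps
`simulate_session()` byte-reproducible for a fixed config.

What the simulator does *not* model: occlusion and head pose (major error
sources on real video), detector box jitter, embedding drift with age,
coder disagreement (gold codes are perfect unless you inject errors with
`corrupt_gold()`), multiple screens, and furniture geometry. Tests that
pass on synthetic sessions therefore validate the measurement logic and
statistics, not the vision networks.

## Calibration choices

**Detector operating point.** `build_roc()` counts true positives by
greedy one-to-one IoU matching per frame (IoU ≥ 0.5, descending-IoU
order — standard detection practice) and normalises false positives by
total recording time. `select_operating_point()` returns the largest
threshold meeting a sensitivity floor (default 0.925) under an FP/s cap
(default 0.79); if the floor is unattainable it maximises sensitivity
under the cap, reflecting the design intent of preferring false positives
(screened later) over missed faces.

**Verification.** The match score is the maximum Pearson correlation
between the candidate embedding and the gallery rows (maximum rather
than mean: robust to pose-diverse enrollment). The default threshold is
0.93. Tracks are built by frame-to-frame greedy IoU association
(threshold 0.3, tracks end after one missing frame), and the raw
threshold decisions are smoothed by a centred majority vote over 15
frames (≈ 1 s at 15 fps) within each track, ties resolving to the raw
decision; at most one face per frame is declared the target (highest
score, ties to the lowest face index). Whether smoothing should act on
scores or decisions is genuinely open; decision-majority was chosen
because it is order-statistic robust and exactly testable against a
brute-force oracle.

**Angular limits.** The frame is partitioned into a 3 × 3 grid of equal
cells ("multiple regions" without a stated count; 3 × 3 is the coarsest
grid that separates left/centre/right and top/bottom viewing geometry).
Per television position, the yaw and pitch windows of each cell are the
central 90% interval (5th–95th percentile) of the angles observed on
frames gold-coded `watching`; cells with fewer than 30 watching frames
inherit the global windows pooled over all cells. Quantile-interval
fitting was preferred to discriminative optimisation as the simplest
estimator consistent with "setting angular limits"; the coverage is a
config parameter. At zero noise the angle distribution is degenerate and
a 5–95% interval would by construction drop 10% of watching frames, so
noiseless calibrations use `coverage_quantile = 1` (full range) — the
consistent limit of the same rule. Both yaw and pitch are constrained by
default; `yaw_only = TRUE` gives the 1-D variant (whether the original
limits were 1-D or 2-D is unstated). Classification is
boundary-inclusive and invariant to positive rescaling of the gaze
vector. `loo_evaluate()` implements leave-one-family-out calibration per
television position, skipping (with a warning) positions represented by a
single family, and `summarise_by_position()` aggregates by family mean —
whether frames should instead be pooled is unstated, so both the
per-family rows and the pooled counts are available.

**Pipeline conventions.** Frames with no verified target contribute "not
viewing" (a frame without the child cannot be a viewing frame, and
missing the child when there is no gaze does not affect the total).
Frames gold-coded `cannot_tell` are excluded from every statistic but the
device still emits a decision for them; `out_of_frame` counts as not
watching in agreement analyses, since viewing operationally requires
presence. `epoch_smooth()` relabels fixed epochs (e.g. 5/15/30 s) by
frame majority with ties counting as viewing, the final partial epoch
contributing its actual duration.

## Statistical machinery

`metrics_from_counts()` applies the confusion-matrix formulas exactly and
propagates zero-denominator cases as `NA` ("undefined"), never as 0 —
strata can legitimately be empty. PABAK is `2·Po − 1`; its optional 95%
CI uses the large-sample normal approximation to the agreement
proportion (the CI construction is not standardised; this one is labelled
as such). Cohen's kappa uses marginal-product chance agreement over any
number of categories.

The frame-level ICC is a two-rater absolute-agreement intraclass
correlation (McGraw–Wong ICC(A,1)) computed by two-way ANOVA variance
decomposition directly on the 0/1 ratings, with frames as the units
nested in their families (at least two families are required and the
family count is recorded). This is a deterministic linear-probability
approximation of a binary-outcome mixed-model ICC; it is exactly testable
against closed-form mean squares, which is why it was preferred to a
GLMM-based estimator, and the divergence is recorded in the report
metadata. The total-time ICC applies the same estimator to
log-transformed per-family totals (durations being naturally lognormal).
Interpretation bands: ≤ 0.35 weak, 0.36–0.67 moderate, ≥ 0.68 high,
≥ 0.9 very high.

`wilcoxon_visits()` tests paired per-family metrics across two visits:
for ≤ 12 non-zero differences the exact two-sided p-value is obtained by
enumerating all sign assignments of the observed absolute differences
(which also handles ties exactly); for ≤ 25 without ties the standard
exact distribution is used; otherwise the normal approximation with tie
correction. All differences zero is reported as a degenerate p = 1 with a
flag rather than an error. `stratified_summary()` reports group means and
SDs of estimated and gold totals with no inferential tests (descriptive
only, as appropriate for small stratified tables); a singleton group's SD
is undefined.

## Problem sizes and numerical conventions

The test-suite and the acceptance script run desk-scale studies: 5-minute
sessions, 8–10 simulated families, with the Markov switch rates raised to
0.05/s (mean bouts ≈ 20 s) so that short sessions contain both states and
every per-family total is positive — the bout length is scaled with the
session length, preserving the per-session number of state changes of a
90-minute observation with multi-minute bouts. Exact-recovery checks use
600-second noiseless sessions; the simulator and pipeline comfortably
process a full 90-minute session at 15 fps in under a minute each.

Conventions worth knowing when extending the package: frame indices are
0-based with half-open duration-coded intervals `[start, end)` (unambiguous
tiling and duration arithmetic); face indices within a frame are 1-based;
all angle arithmetic is in degrees; quantiles use R's default type 7;
window boundaries are inclusive; IoU-based matching breaks ties by the
order `which.max` scans the IoU matrix; serialization writers emit 17
significant digits so that `read(write(x))` reproduces doubles exactly.

## Known limitations

* The simulator's error structure is stylised; in particular verification
  errors are driven purely by isotropic embedding noise, so impostor
  acceptances (sibling mistaken for target) are essentially absent at the
  default 45° centroid separation — real systems see them under occlusion.
* The frame-level ICC is a linear-probability approximation; for strongly
  unbalanced prevalence it can differ from a binary-GLMM ICC.
* Angular-limit fitting assumes the training families cover the seating
  positions of the held-out family; a family seated where no training
  family ever sat inherits windows from other cells via the global
  fallback, degrading gracefully rather than failing.
* `tv_position = "other"` requires user-supplied screen geometry and
  cannot be pooled with calibrated positions.
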