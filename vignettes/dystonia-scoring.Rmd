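---
title: "Scoring dystonia from stick-figure videos: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dystonia from stick-figure videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyskscore)
```

## The problem

Dystonia in dyskinetic cerebral palsy — sustained abnormal postures and slow
involuntary movements — is assessed clinically from standardized videos using
the Dyskinesia Impairment Scale (DIS). Scoring is slow, requires training and
remains subjective. This package implements an automated alternative: given
the 2D pixel coordinates of 12 body landmarks (left/right wrist, elbow,
shoulder, hip, knee, ankle) extracted per frame by a markerless tracker, it
computes geometric posture features and regresses the normalized DIS
amplitude score (0, 0.25, 0.5, 0.75, 1) with a random forest, evaluated by
subject-grouped cross-validation so that model-vs-rater error can be compared
with rater-vs-rater error.

The package consumes keypoint tables; running or training the pose-estimation
network itself is out of scope, as are video decoding, other DIS items
(duration sub-scores, distal limbs, trunk, choreoathetosis) and dystonia
during activity.

## The data model

A `PoseSequence` (an S4 extension of `SummarizedExperiment`) holds one
video: rows are the 12 landmarks, columns are frames, and four assays carry
x, y (image coordinates in the standardized 720×575-pixel frame, origin
top-left, y downward), the tracker likelihood in [0, 1], and a logical
missing mask. Recordings are nominally 20 s at 25 Hz (500 frames); lying
videos are sometimes shorter.

## Preprocessing

Three steps run in a fixed order (`preprocessPose()`), because the feature
stage must see a complete, fixed-length sequence:

1. **Likelihood cutoff** (`pCutoff`, default 0.8): points with likelihood
   strictly below the cutoff are masked; the boundary value is kept,
   matching the usual tracker convention. Coordinates are never altered, so
   the operation is idempotent and monotone in the threshold.
2. **Gap interpolation**: interior masked runs are filled linearly per
   coordinate between the flanking observed frames; leading/trailing runs
   hold the nearest observed value. Observed points stay bit-identical. The
   reference protocol retrained its tracker until tracking was visually
   acceptable and states no repair policy for the remaining low-likelihood
   points; interpolation is this package's own choice, made so the cutoff
   path composes with feature extraction.
3. **Cyclic extrapolation** (`targetLength`, default 500): short sequences
   are extended by repeating existing frames in order (frame *i* of the
   output is input frame *i* mod *n*). Tiling is the simplest deterministic
   reading of "adding the existing frames" that preserves the within-video
   dynamics; it also preserves each landmark's mean position exactly when
   the target is a multiple of the input length. Longer-than-target input is
   refused rather than silently truncated. Extrapolation runs before
   windowing, so the 10 windows always cover 50 frames each.

## The three posture features

For each frame and each body side, three quantities derived from the
clinical definition of dystonia (sustained abnormal posture, slow movement):

* **distance-to-middle-point** `d2m(t) = ‖p(t) − p̄‖`: the pixel distance of
  a landmark from its own mean position over the whole (extrapolated)
  video. The mean is taken over all `targetLength` frames so every feature
  sees the same support.
* **distance-to-line**: the perpendicular distance from a landmark to the
  *infinite* line through the same-side shoulder and hip in that frame.
  The protocol draws a single shoulder–hip bodyline without fixing the side;
  using the ipsilateral line keeps the feature mirror-symmetric, which the
  two-samples-per-video construction requires. The infinite line (not the
  segment) is used because segment clamping would introduce kinks.
* **joint angle**: the interior angle at the elbow (wrist–elbow–shoulder,
  sitting) or knee (ankle–knee–hip, lying), in degrees in [0, 180], with the
  cosine clamped to [−1, 1] before `acos`. As a 2D projection it is not the
  anatomical joint angle; the projection error is accepted, not corrected.

Landmark sets depend on the rest position: sitting videos measure the arm
(d2m of wrist, elbow, shoulder; d2l of wrist, elbow; elbow angle), lying
videos the leg (d2m of ankle, knee, hip; d2l of ankle, knee; knee angle).
Each of the 6 traces is reduced to the medians of 10 equal windows (2 s
each; even-length windows take the mean of the two central order
statistics), giving a 60-value vector per side in a fixed documented order
(`d2m_*`, then `d2l_*`, then `angle_*`). All three features are invariant
under translation, rotation and reflection applied uniformly to every frame
— tested to 1e-9 — so left and right sides are treated as two samples of
one geometry.

## Scores, model and evaluation

Raw DIS amplitude scores (0–4) are normalized by the item maximum to
{0, 0.25, 0.5, 0.75, 1}. A random-forest regressor
(`ScoringConfig(nTrees = 100)`, squared-error splitting, trees grown without
a depth limit) maps the 60 features to the continuous normalized score.
`mtry` is set to the full feature count, matching the reference regressor's
default of considering all features at each split; the terminal node size
stays at this implementation's regression default (5), a minor difference
from the reference learner noted here once.

Evaluation uses 5-fold cross-validation grouped by subject: all samples of a
patient — and hence both side-samples of each video — share a fold, so no
model is ever tested on a subject it trained on (asserted programmatically).
The fold splitter assigns subjects greedily in descending sample count to
the currently smallest fold, with a seeded shuffle breaking ties; it
balances fold sizes and is deterministic given the seed. Errors are pooled
over all out-of-fold predictions (not averaged per fold): pooling uses every
sample exactly once and pairs naturally with reporting the sample SD of the
absolute errors. Pooled MAE equals the size-weighted mean of per-fold MAEs,
which the tests verify as an identity. For confusion matrices, continuous
predictions are snapped to the nearest normalized level, exact midpoints
rounding toward the lower (clinically conservative) severity; values are
clamped into [0, 1] first.

Because raters disagree, a separate model is trained and evaluated per
rater and item (`trainPerRater()`); inter-rater agreement on the same
normalized scale (`interRaterMae()`, computed on the key intersection only)
provides the human reference level. One seed in `ScoringConfig` drives fold
shuffling and the forests (fold *f*'s forest uses `seed + f`); forest MAEs
move by roughly ±0.01–0.02 across seeds, which is reported, not suppressed.

## Tracking accuracy

`trackingMae()` scores the tracker itself: the mean Euclidean pixel distance
between predicted and manually labeled points, unweighted across all matched
frames and bodyparts, optionally excluding predictions below a likelihood
cutoff. Only keys present in both sets are evaluated. At the standardized
frame's resolution of 0.4 cm per pixel, `pixelsToCm()` converts to
centimetres (e.g. 4.49 px → 1.8 cm).

## The synthetic cohort generator

Clinical keypoint data cannot ship with the package, so `generateCohort()`
produces stick-figure cohorts with known ground truth that exercise every
stage:

* base postures for lying (supine, horizontal body axis) and sitting
  (upright) inside the 720×575 frame;
* **severity mapping**: the distal landmarks (ankle/knee lying, wrist/elbow
  sitting) drift around the base posture with an RMS excursion of
  `amplitudePerLevel` (25 px) × level — linear in the level because DIS
  amplitude is defined as a percentage of range; proximal landmarks are
  static up to jitter;
* **dynamics**: a Gaussian random walk smoothed with a 3 s moving average
  and rescaled to the target RMS — the simplest process producing slow,
  sustained excursions that windowed medians can see (the same number of
  random draws is consumed at every level, so sequences at different levels
  are comparable under a shared seed);
* white pixel jitter (sd 1.5 px) on every point, a 2% dropout fraction with
  likelihood drawn in [0, 0.8) (the rest in [0.8, 1]) so the cutoff path is
  exercised, and reflective clamping at the frame borders;
* per-subject latent levels drawn uniformly over 0..4, held constant across
  a subject's videos as a stable impairment would be;
* `simulateRater()` adds rounded, clamped Gaussian noise to the raw scores,
  giving a controllable disagreement level whose expected MAE the tests
  check against a closed-form enumeration.

What the simulator does **not** emulate: choreoathetotic (fast, recurring)
movements, camera-angle variation, soft-tissue and clothing occlusion
structure, rater bias that depends on context rather than noise, and the
unbalanced severity distribution of a real cohort. Passing the recovery
tests therefore shows that the pipeline's machinery is correct and that the
features separate amplitude-scaled slow excursions; it does not certify
clinical accuracy, which requires the deposited clinical coordinates.

## Problem sizes and test design

The validation suites run at the study's own scale where that is cheap:
recovery uses cohorts of 34 subjects × 3 videos (204 samples after the side
split) at the default spec, averaged over 5 seeds, and requires pooled MAE
≤ 0.15 and Spearman ρ ≥ 0.8 between predicted and true scores; a
permutation-null cohort (targets shuffled) must do no better than predicting
the mean. Geometry is checked against independent oracles: brute-force
search along the line for distance-to-line (100 random instances, 1e-6),
closed-form angles, and isometry invariance of the entire feature vector at
1e-9. Smaller fixtures (30–100 frames) are used wherever frame count is not
the point.

## Known limitations

* Cyclic tiling repeats dynamics; for very short videos (a few seconds) the
  window medians become copies and the effective information is lower than
  the 60 features suggest.
* The 2D joint angle conflates posture change with camera projection.
* Forest predictions are bounded by the training target range, so a cohort
  without level-4 samples can never predict 1.0.
* With ~200 samples, per-fold MAE varies noticeably; single-seed MAEs
  should be read with the ±0.01–0.02 seed spread in mind.
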