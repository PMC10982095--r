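---
title: "Methods: coding and classifying bodily cues to deception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding and classifying bodily cues to deception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodycues)
```

## The problem

In a deception interview study, each interviewee sits opposite an
interviewer and answers questions either honestly (truth condition) or
deceptively (lie condition). Inertial motion capture records the 3D position
of 23 body joints at 60 Hz for roughly 2.5 minutes per session, and each
interviewee is recorded twice: once in a *Game* session (reverse-order
questions about a computer game) and once in a *Wallet* session
(normal-order questions about delivering a wallet). The question this
package addresses is whether, and through which coding choices, simple
per-feature statistics of body pose and movement can distinguish truthful
from deceptive sessions — not whether a black-box classifier can maximize
accuracy. Every modeling choice is therefore deliberately transparent:
univariate Gaussian class models, significance-filtered majority voting, and
subject-disjoint cross-validation.

## Spatial and temporal normalization

Raw joint positions are normalized in three steps, in a fixed order:

1. **Decimation to 5 Hz.** Every 12th frame is kept, starting at the first.
   Decimation (rather than averaging) preserves instantaneous postures;
   since features are later aggregated over windows, the difference between
   the two is largely absorbed by the window statistics. Averaging is not
   offered as a code path; the decimation step errors on non-divisible
   rates rather than silently interpolating.
2. **Root-relative coordinates.** The pelvis position is subtracted from
   every joint in the same frame and the pelvis is dropped, leaving a
   66-dimensional (22 joints × 3) body-centred representation. Whole-body
   translation can therefore never masquerade as body movement.
3. **Segment-length standardization.** Each posture is rebuilt from the
   root outward, placing every joint at its parent's rebuilt position plus
   the *original direction* of the segment times the corpus-average length
   of that segment. This removes differences in body dimensions between
   subjects while preserving joint directions exactly. Reference lengths
   are computed **once per corpus**, not per cross-validation fold: the
   transformation uses no subject-identity or condition information, so it
   cannot leak labels; a per-fold recomputation would only add variance.
   A zero-length input segment makes the direction undefined and is treated
   as a data error — it cannot arise from valid capture.

The full normalization is invariant to global rigid translations by
construction, and all downstream features are additionally invariant to
global rotations because they are built from distances and angles of
body-relative positions. The test suite asserts this invariance at `1e-9`.

The canonical skeleton (axial chain pelvis–L5–L3–T12–T8–neck–head; arm
chains T8–shoulder–elbow–wrist–hand; leg chains pelvis–hip–knee–ankle–toe)
is shipped as a YAML file. It matches the 23-segment output of common
inertial capture suits and yields exactly the documented feature counts: 22
movement joints, 9 angle joints, 11 distance pairs, and 8 + 6 symmetry
comparisons.

## The 67 features

Four feature types are computed per frame (or frame pair):

* **Movement (30).** Euclidean displacement of each non-root joint between
  consecutive 5 Hz frames (22), totals per body part (6), an upper-body
  total (arms + torso + head), and a full-body total. Totals are sums of
  their member joints, a conservation property the tests check exactly.
* **Joint angle (10).** At the neck, shoulders, elbows, hips and knees: the
  angle between the incoming segment (parent→joint) and outgoing segment
  (joint→child), in degrees. Under this convention a fully extended chain
  reads 0° and a fully folded one 180°. The tenth feature is the mean of
  the nine.
* **Joint distance (12).** Eleven fixed pairs — head to either elbow, the
  two hands, crossed hand–elbow pairs, same-side hand–knee pairs, knee–knee,
  ankle–ankle, and pelvis to either ankle — plus their mean. "Hand" means
  the hand joint, not the wrist. These capture posture compactness, face
  touches and leg configuration.
* **Symmetry (15).** Positions are mirrored in the plane through the root
  whose normal is the unit vector between the hips. Eight features compare
  the mirrored left joint of each left/right pair with its actual right
  counterpart; six compare each midline joint with its own mirror image
  (twice the distance to the plane); the fifteenth is the mean of the
  fourteen. A perfectly symmetric pose scores zero everywhere. Only left
  limbs are compared against mirrored right ones, since the pair distances
  are symmetric in the two sides.

The catalogue links every feature to the body parts its joints belong to;
features that average over all joints are linked to all six parts. Features
touching one part are classed `single`, exactly two `two`, and three or more
`all` — the upper-body and full-body totals and the three mean features.
A three-way class with "two or more" would not tile the catalogue, because
the upper-body total touches four of the six parts.

## Window aggregation

Feature streams are cut into consecutive, non-overlapping windows (whole
session, 60, 30, 10, 5, or 1 s at 5 Hz). A trailing remainder shorter than
the window is dropped rather than padded, so no window carries statistics of
a different sample size. Movement streams live on frame pairs and are
assigned to windows by the later frame of each pair, which makes the
assignment unambiguous and non-overlapping; the first window of a session
therefore has one fewer movement sample. Each feature is summarized per
window by mean, minimum, maximum, range and standard deviation (sample,
n−1 denominator — consistent with the classifier's sample estimates),
giving 67 × 5 = 335 dimensions regardless of window length. The "2.5 min"
setting is implemented as exactly one window spanning the whole recording,
since recorded sessions are only approximately 2.5 minutes.

## Classification

For every window feature independently, a Gaussian is fitted per class on
the training windows (sample mean, sample sd) and a test value is assigned
to the class with the larger density, with equal priors. Equal priors match
the balanced lab design; a real-world deployment would face a much lower
prior probability of deception, and this implementation deliberately does
not pretend to calibrate for that. Degenerate fits (zero class sd) are
floored at `1e-9` times the feature's pooled training sd so the density
comparison stays defined; such features also receive p = 1 in selection, so
they never carry weight. Exact density ties and exact vote ties resolve to
"truth" — deterministic, and in the conservative direction (a truth bias
reduces false accusations at the cost of missed lies).

Votes are combined by majority over one of three feature sets: *all* (335),
*stat-95*, or *stat-99* — the features whose truth/lie training
distributions differ in a two-sample test at p < 0.05 or p < 0.01. The test
is **Welch's t-test** by default: the per-class variances have no reason to
be equal, and Welch is the safe default among the tests the procedure could
plausibly have used. Student's t and the Wilcoxon rank-sum test are
available via `method =`, and the choice should be calibrated against the
recorded corpus (via the stat-95 selection sizes it reproduces) when that
corpus is mounted. Feature significance ranking (for top-k experiments)
sorts by ascending p-value with ties broken in catalogue order, making
top-k lists proper prefixes.

Evaluation is leave-one-interviewee-out: each fold trains on every other
interviewee's windows and tests on the held-out interviewee's windows, so
train and test subjects are always disjoint (an assertion inside the fold
builder enforces this). With sub-session windows, every window is classified
and scored independently; no session-level fusion is applied, because the
choice of fusion rule would itself be a modeling decision the simple
protocol avoids. The reported detection rate is the mean of per-fold
accuracies.

## Experiments

The experiment layer reuses one set of per-fold computations (p-values and
vote matrices) and rescopes them: train/test crossings over
both/Game/Wallet; the window-length sweep; selected-percentage and rate
breakdowns by feature type, window type, linked body part, and body-part
count; the top-k sweep (k = 1..200 by default); per-feature ranking without
voting; and the measurement-noise sweep. Noise is added to the aggregated
test-window features, not to raw coordinates, as zero-mean Gaussian with sd
equal to `r` times the feature's training sd. The training sd is taken as
the **pooled** (class-agnostic) per-fold sd: the natural reading would use
the class-conditional sd, but the true class of a test window is exactly
what is unknown at test time, so conditioning the corruption on it would be
incoherent as a measurement-noise model; the class-conditional variant
remains available (`sd_basis = "class"`) for sensitivity analysis. Noise
rates average 100 seeded repetitions by default, and `r = 0` reproduces the
noiseless rates exactly, repetition for repetition. Selected-feature
percentages are averaged over folds, since selection is refitted per fold.

## The synthetic corpus generator

The generator exists so the entire pipeline — including its statistical
behavior — is testable without any recorded interviews. It emulates:

* **seated postural sway**: independent AR(1) processes (coefficient 0.99
  at 60 Hz, Gaussian innovations of scale `sway_sd` = 2 mm, stationary
  initialization) on every joint coordinate, giving smooth,
  centimeter-scale idle motion;
* **sparse gestures**: Poisson-arriving bursts (rate 0.05/s, i.e. one per
  20 s) that displace one arm chain along a random direction with a
  raised-cosine envelope (1 s, 8 cm peak at the hand, tapering toward the
  shoulder), concentrating discretionary movement in the arms;
* **the deception effect**: in lie-condition sessions, the sway innovation
  scale and the gesture rate are multiplied by `lie_movement_multiplier`.
  The template pose itself never changes. This is the simplest mechanism
  consistent with the finding the design builds on — an overall increase in
  body movement, in every limb, when lying;
* **the paired design**: each interviewee receives one condition by a
  seeded permutation (balanced, so `n_interviewees` must be even) and is
  recorded in one Game and one Wallet session, 150 s at 60 Hz.

The multiplier defaults to 1.0 (no effect), which makes the generator a
null model: truth and lie sessions are then draws from the same process,
and the pipeline's cross-validated rate must sit at chance. The package's
end-to-end checks use exactly this: chance-level rates at multiplier 1
(within 50% ± 10 points averaged over 20 corpora of 20 interviewees),
reliable detection at multiplier 2, and a rate that is non-decreasing in
the multiplier.

What the generator does **not** emulate: biomechanically realistic motion
(joint coordinates sway independently, so limb rigidity holds only on
average), speech- or question-locked movement structure, interviewer
influence, posture shifts, any asymmetry between Game and Wallet sessions,
and — importantly — between-subject variation in baseline movement: all
simulated interviewees share the same sway and gesture parameters. Because
of that last simplification, whole-session aggregation measures the
condition multiplier almost noiselessly, and synthetic detection rates
saturate at 100% for effect sizes well below what real, heterogeneous
subjects would require. Consequently, passing the synthetic checks demonstrates that the
pipeline is statistically sound (no label leakage, correct null behavior,
sensitivity to a genuine between-condition movement difference) — it does
not certify the recorded-corpus detection rates, which depend on the real
data and are checked separately when that corpus is available. No
quantitative per-limb effect sizes are available to calibrate the
generator, so the effect size is an explicit configuration parameter rather
than a claimed property of deceptive behavior.

## Numerical choices and degenerate inputs

* Segment scaling errors on zero-length segments; the symmetry features
  error when the hips coincide (mirror plane undefined); resampling errors
  on non-divisible rates. Errors are typed (`bc_*` condition classes), not
  silent fixes.
* Windows need at least 2 samples per feature; a 1 s window at 5 Hz (5
  samples, 4 movement samples in the first window) is the shortest
  supported study setting.
* Degenerate selection: if the significance filter selects nothing in a
  fold, scoring stops with an explicit error rather than silently falling
  back to another feature set. At study-scale corpus sizes this does not
  occur; tiny corpora should use `alpha = 1`.
* Ties: density ties and vote ties go to "truth" (see above); p-value ties
  in ranking go to catalogue order.
* All stochastic components (generator, condition assignment, noise
  repetitions) are driven by explicit integer seeds; identical
  configuration and seed give bit-identical output.

## Problem sizes used in the shipped checks

The package's own end-to-end checks run the full pipeline at the study's
recording conditions (150 s × 60 Hz sessions): 20 corpora of 20
interviewees for the null calibration, 10 seeds per arm for the multiplier
sweep, 10 corpora of 12 interviewees for the noise-degradation trend (20
noise repetitions per factor there; the standalone noise experiment
defaults to the study's 100), and one 20-interviewee corpus for the
window-length comparison. The null-calibration and multiplier-sweep arms
vote over all 335 features (`alpha = 1`), since on a null corpus the
significance-filtered sets can legitimately be empty in a fold; the
detectability check at multiplier 2 uses the stat-95 protocol. Unit tests
use shorter sessions where the property under test does not depend on
session length.

## Known limitations

* The majority vote ignores correlations between features; this is by
  design (interpretability), and means reported rates understate what a
  multivariate classifier could reach.
* Window-level scoring for sub-session windows is one of several defensible
  protocols; session-level fusion is deliberately not implemented.
* The two-sample test behind stat-95/stat-99 is a package choice (Welch);
  reproducing published selection sizes exactly may require the Student
  variant, which is why the test is configurable.
* The CSV dialect is package-native. Recorded corpora in other layouts must
  be mapped through a YAML column-mapping dialect; no proprietary capture
  formats are parsed.
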