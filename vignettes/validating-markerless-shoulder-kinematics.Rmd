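---
title: "Validating marker-less shoulder kinematics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating marker-less shoulder kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoulderkin)
```

`shoulderkin` answers a practical question in tele-rehabilitation: if a
clinic replaces a marker-based optical motion-capture (mocap) system with a
depth camera and a skeleton-tracking SDK, how trustworthy are the joint
angles it reports, and how much does a per-patient regression calibration
help? This vignette is the package's own account of the models behind that
answer: the kinematic simulation, the angle definitions, the agreement
battery, and the calibration protocol, together with the parameters that
matter and the choices we made where the design was genuinely open.

## The measurement model

A trial is one subject performing repetitions of shoulder abduction (left,
SAL, or right, SAR) while standing at a fixed distance from a depth camera.
Coordinates are camera-centered: x lateral (subject's left positive), y
vertical up, z depth toward the subject; the camera sits 1 m above the
ground, so ground level is y = −1.

`simulate_truth()` produces the noiseless skeleton. The exercising arm
stays in the subject's frontal plane with the elbow fully extended
(shoulder, elbow and wrist exactly collinear) and follows a raised-cosine
abduction profile per repetition,

$$\alpha(t) = \alpha_{peak}\,\frac{1 - \cos(2\pi t / T)}{2},$$

which starts and stops with zero angular velocity — how people actually
move — and places its peak exactly mid-repetition on the sampling grid
(integer-second segment durations at 256 fps), so the sampled maximum
equals the scripted peak without interpolation error. Movement speed is a
per-subject parameter (`rep_duration`, default 4 s per repetition); real
cohorts differ mainly in that slope.

Anthropometry is derived deterministically from standing height via fixed
ratios (`anthropometric_ratios`): upper arm 0.186 h, forearm 0.146 h,
shoulder half-width 0.129 h, chest/shoulder landmark height 0.72 h. One
choice here is deliberate and load-bearing: **the chest marker sits at
shoulder height**. The chest landmark is the sternal notch, which is
anatomically at clavicle level, and the consequence is that the virtual
shoulder (below) coincides with the physical shoulder on noiseless
frontal-plane data, making the computed α equal the scripted profile
exactly. With a lower chest marker the noiseless α would top out above 90°
by a geometry-dependent amount, which is not what a calibrated analysis
should anchor on.

### The two observers

`observe_mocap()` emulates the reference system: resampling to 256 fps,
rigid anatomical marker offsets, and small i.i.d. Gaussian noise (default
sd 1 mm). The elbow marker is displaced 0.03 m posteriorly in the local
segment frame (it physically sits on the back of the elbow), and the offset
rotates with the limb. For an extended arm this displacement bends the
apparent elbow angle by the closed-form amount
$\beta = 180° − \arctan(c/l_{ua}) − \arctan(c/l_{fa})$
(about 167.7° for a 1.70 m subject at c = 0.03 m), a stable,
geometry-explainable offset of the class real mocap elbow markers produce.
The exact real-world magnitude depends on marker geometry we cannot know,
so it is a tunable profile parameter, not a claim.

`observe_sdk()` emulates the depth-camera tracker: resampling to 30 fps,
per-axis noise sd

$$\sigma(d) = \sigma_{2m} \left(\frac{d}{2\,\mathrm{m}}\right)^{p},$$

with $\sigma_{2m}$ = 8 mm and p = 1.5 by default, and velocity-dependent
dropouts: in frames where the exercising arm moves faster than
`dropout_speed_threshold` (default 60°/s, just below the default profile's
70.7°/s peak speed), the elbow and wrist of that arm are lost together with
probability `dropout_probability` (default 0.2) — the motion-blur failure
mode of skeleton SDKs. The noise parameters are free parameters of the
synthetic world, chosen so the distance trend is clearly visible without
drowning the signal; every acceptance property either measures the
generator's own parameters back or runs noise-free, so conclusions do not
hinge on their exact values.

### What the generator does and does not emulate

It reproduces the statistical structure the downstream analysis assumes:
two frame rates, anatomical marker offsets, distance-dependent keypoint
noise, velocity-dependent dropouts, per-subject speed and anthropometry.
It does **not** emulate soft-tissue artifact, marker slippage over a trial,
out-of-plane compensation movements, occlusion geometry, lighting effects,
or SDK-specific biases that depend on training data. Passing tests
therefore demonstrate that the *pipeline* is correct and well-calibrated
under the stated error model — not that any particular camera achieves a
particular accuracy on patients.

## The three angles

All three angles reduce to `vector_angle(u, v)`, the arccosine of the
clamped normalized dot product, in [0°, 180°]. Clamping the cosine to
[−1, 1] absorbs rounding; note that because arccos has unbounded slope at
±1, a cosine rounded at machine precision can move an angle near 0° or
180° by up to ~1.5 × 10⁻⁶ degrees — the package's tests treat that as the
floating tolerance for boundary anchors.

- **α** = angle between (virtual shoulder → elbow) and world-down (0,−1,0).
  The arm-vector endpoint is the elbow, matching how the shoulder angle is
  drawn on skeleton overlays; with the elbow extended the wrist endpoint is
  equivalent and remains selectable. World-down (not a trunk axis) is the
  reference because the marker set has no pelvis landmark; subjects stand
  upright, and trunk lean is a documented limitation.
- **β** = angle at the elbow between the physical shoulder and the wrist.
  The *physical* shoulder, not the virtual one: the virtual construction
  exists to make the two systems commensurable for α, whereas β is a
  property of the true limb segments.
- **γ** = angle between the arm vector and the frontal-plane normal,
  estimated per frame as the unit cross product of the shoulder-to-shoulder
  vector with world-down, falling back to the camera depth axis when the
  shoulders are degenerate — for a camera-facing subject the two coincide.

The **virtual shoulder** takes the physical shoulder's lateral coordinate
and the chest marker's height and depth. "Lateral" is the only reading of
the construction consistent with taking height *and* depth from the chest.

### Gap filling

`locf_fill()` implements last-observation-carried-forward: an invalid
required joint inherits its most recent valid position; frames before a
joint's first detection have nothing to carry and are dropped; a joint that
is never valid makes the trial unrecoverable. Filled observations stay
flagged per frame and per joint, and an angle sample is flagged whenever
any contributing joint was filled — this flag is what lets the analysis
separate dropout-corrupted frames from clean ones later. LOCF is
idempotent by construction.

## Alignment and agreement

The comparison rate is 30 fps — the slower stream's native rate — so the
reference is downsampled (linear interpolation, no extrapolation) rather
than the test stream upsampled into invented detail. Synchronization
maximizes the cross-correlation of the mean-removed α signals over integer
sample shifts within ±2 s, breaking ties (including constant signals)
toward zero lag, and applies the same shift to β and γ. Alignment never
changes sample values, only indexing and trimming. No smoothing filter is
applied anywhere by default: the raw fluctuations are part of what the
agreement analysis measures.

`agreement_metrics()` reports MAE, RMSE, R², Spearman ρ, and the mean and
sd of differences. Two conventions deserve a note:

- **R² is the squared Pearson correlation** between test and reference,
  not 1 − SSres/SStot about the identity line. Only the correlation
  reading can sit near 1 while MAE is several degrees (a pure bias leaves
  it at exactly 1), which is the regime this kind of validation reports.
  The identity-line variant is implemented and selectable (`r2 =
  "identity"`).
- **All reported sds are population (divide-by-N)** — the convention the
  packaged cohort table's printed summary row follows — with the sample
  convention available through `stats::sd()`.

Difference plots are Bland–Altman style: per-sample difference against the
mean of the two methods (the best estimate of the true value), with mean
and mean ± sd lines.

For the distance effect, the Friedman matched unit is one summary value
per subject per distance (per-trial MAE), not per-frame samples: frames
are heavily autocorrelated and their counts differ across distances, so
frame-level Friedman would be anticonservative and ill-matched. Post-hoc
pairwise Wilcoxon signed-rank tests use Bonferroni correction over the
three distance pairs. Degenerate inputs are defined, not fatal: all-tied
Friedman columns give statistic 0 and p = 1, all-zero Wilcoxon differences
give p = 1, and constant samples make the normality battery return NA with
a warning. The Kolmogorov–Smirnov normality test uses moment-estimated
mean and sd, which is conservative; Shapiro–Wilk runs on a deterministic
evenly-spaced subsample when n exceeds its 5000-sample limit.

## Personalized calibration

Calibration is strictly stratified: one univariate regression per subject ×
exercise × distance, mapping SDK α to reference α at the frame level, fitted
on a seeded shuffled 80/20 split and evaluated only on the held-out 20%
next to the uncalibrated identity baseline on the same indices. A distance
feature would be redundant — strata are distance-specific by construction.

The ten families and their fixed defaults:

| family | backend | defaults |
|---|---|---|
| LR | `stats::lm` | — |
| RR / LaR / ER | `glmnet` | penalty 1.0 / 0.01 / 0.01, mixing 0.5 |
| SVR (linear / RBF) | `e1071::svm` | cost 10, ε 0.1; RBF γ = 1/var(x) |
| DT | `rpart` | max depth 6, cp 10⁻⁴ |
| RF | `ranger` | 200 trees, min node size 1 |
| GB | `xgboost` | 200 rounds, learning rate 0.1, depth 3 |
| PR | `stats::lm` + `poly` | degree 3 |

Two conversion details matter for reproducing the intended behavior.
Penalties are expressed **per observation** (glmnet's λ is set to
penalty/n), so the defaults are weak by design and the four linear families
collapse numerically onto ordinary least squares on well-conditioned strata
— the tied-linear-families behavior the comparison is expected to show.
And `e1071::svm` is called with `scale = FALSE`: x and y share units
(degrees), and autoscaling y would silently turn the ε-tube into ~2.6° at
typical abduction spreads, changing the estimator class the defaults
describe. All stochastic fitters are seeded per stratum by a documented
integer hash of the global seed and the stratum identity, so the full
comparison grid is bit-reproducible; failed strata are recorded and
skipped rather than aborting the grid.

One property ties calibration back to gap filling: dropout-corrupted frames
carry no information about the true angle (the elbow is frozen mid-motion),
so no regression can repair them — calibrated residuals on LOCF-flagged
frames remain above those on clean frames. The test suite asserts exactly
this irreversibility.

## Numerical choices and problem sizes

- Angles in degrees everywhere; radians never surface in files or returns.
- Trajectory CSVs are long-format text with a commented `key=value` header
  block, written at 10 significant digits (round trips to ≤ 1 nm); a
  binary mocap importer is out of scope but the column semantics make one
  trivial to add.
- Determinism: every random stream (observer noise, dropouts, splits,
  stochastic fitters) is derived from one seed plus string keys through a
  31-bit hash; identical configurations produce byte-identical result
  files.
- Test-suite problem sizes were chosen to exercise each property at the
  scale the pipeline actually runs: the oracle-equivalence check uses 10⁴
  random poses at 10⁻⁹ degrees; the distance-trend check runs the full
  14-subject cohort at three distances over 20 seeds (SAL arm); the
  statistical-battery calibration uses 1000 null replicates of 20 matched
  units; calibration properties use strata of 500–600 frames, the size
  class of one real trial (~780 aligned samples). The identity-data
  sub-0.5° check runs at that trial-sized n because piecewise-constant
  learners (gradient boosting) have an interpolation floor that scales
  with the training-point gap.

## Known limitations

- Body-down is the camera vertical; a leaning trunk biases α.
- The frontal-plane normal assumes visible, tracked shoulders; its camera
  axis fallback is only exact for a camera-facing subject.
- The cohort roster drives anthropometry through height alone; limb
  proportions do not vary between subjects of equal height.
- LOCF is the only gap-filling rule implemented — by design, since its
  downstream signature (plateaus, irreversible information loss) is part
  of what the analysis studies.
- The synthetic world's noise magnitudes are plausible, not fitted to any
  specific camera; absolute MAE values from simulations characterize the
  pipeline, not a device.
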