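# shoulderkin

Validation and calibration toolkit for marker-less upper-limb joint-angle
estimation, aimed at tele-rehabilitation researchers who want to know how well
a depth-camera skeleton tracker measures shoulder kinematics compared with a
marker-based optical motion-capture (mocap) reference — and how much a
per-patient regression calibration can recover.

The real experiment this emulates — participants performing shoulder
abduction in front of both a depth camera and a mocap system — produces
recordings that are rarely shareable. `shoulderkin` therefore ships a
forward-kinematic simulator that reproduces the *statistical structure* of
such paired recordings (frame rates, anatomical marker offsets,
distance-dependent keypoint noise, velocity-dependent dropouts) so the whole
analysis chain is reproducible end to end, and every analysis component works
identically on imported real trajectories.

## The angles

For each arm, three angles are computed per frame from named 3D keypoints
(x lateral, y up, z depth):

- **α (shoulder abduction)** — angle between the arm vector and body-down:
  `α = arccos( v̂ · (0,−1,0) )` with `v = elbow − virtual_shoulder`.
  0° hanging, 90° horizontal.
- **β (elbow extension)** — angle at the elbow between
  `shoulder − elbow` and `wrist − elbow`; 180° when fully extended.
- **γ (arm–body transverse)** — angle between the arm vector and the
  frontal-plane normal `n̂ ∝ (shoulder_R − shoulder_L) × (0,−1,0)`;
  90° while the arm stays in the frontal plane.

Because the two systems place their shoulder landmarks differently, α uses a
**virtual shoulder**: the physical shoulder's lateral coordinate combined
with the chest marker's height and depth, so both systems measure the same
angle. Frames where the tracker loses a joint are repaired by
last-observation-carried-forward (LOCF) before any angle is computed, and
every repaired sample stays flagged downstream.

Agreement between the 256 fps mocap-like stream and the 30 fps SDK-like
stream is quantified after resampling to a common 30 fps grid and
cross-correlation synchronization: MAE, RMSE, R² (squared Pearson
correlation), Spearman ρ, Bland–Altman difference-plot data, Friedman tests
across camera distances with Bonferroni-corrected Wilcoxon post-hocs, and
Shapiro–Wilk / Kolmogorov–Smirnov normality checks. Personalized calibration
fits, per subject × exercise × distance, a univariate regression from SDK α
to reference α on a shuffled 80/20 split, across ten regressor families
(LR, ridge, lasso, elastic net, linear SVR, decision tree, random forest,
gradient boosting, cubic polynomial, RBF SVR).

## Worked example

Simulate one trial (subject S1, left shoulder abduction at 2 m), observe it
with both systems, align, and score:

```r
library(shoulderkin)

subject <- cohort_subjects()[["S1"]]
config  <- trial_config(subject, exercise_script("SAL"), distance = 2.0, seed = 42)
trial   <- simulate_trial(config)                 # truth + mocap + sdk streams
aligned <- analyze_trial(trial$mocap, trial$sdk)  # LOCF, angles, resample, sync
trial_metrics(aligned)
#>   angle arm   subject exercise distance   mae  rmse       r2 spearman
#> 1 alpha L     S1      SAL             2  2.29  2.75 0.996      0.964
#> 2 beta  L     S1      SAL             2  7.66  8.17 0.000703  -0.0258
#> 3 gamma L     S1      SAL             2  5.94  6.41 0.00225    0.0437
```

α tracks the reference closely (MAE 2.3°, R² ≈ 1): the abduction sweep
dominates the noise. β and γ barely move during this exercise, so their R²
is near zero by construction while their MAEs stay small; β's ~7.6° mean
offset is the anatomical elbow-marker displacement of the mocap reference,
γ's offset reflects depth noise around the 90° in-plane value. Calibrating
this stratum:

```r
p   <- aligned_pair(aligned, "alpha")
ds  <- calibration_dataset(p$test, p$reference,
                           meta = list(subject_id = "S1", exercise = "SAL",
                                       distance = 2, arm = "L"))
cmp <- run_model_comparison(list(ds), seed = 42)
cmp$by_family[, c("family", "test_mae_mean", "baseline_mae_mean")]
#>    family     test_mae_mean baseline_mae_mean
#>  1 DT                  1.61              2.17
#>  2 ER                  1.61              2.17
#>  3 GB                  1.44              2.17
#>  ...
#>  9 SVR_RBF             1.26              2.17
#> 10 SVR_linear          1.60              2.17
```

Every family beats the uncalibrated baseline (2.17° → 1.3–1.6°), and the
four linear families are numerically tied — the weak default penalties
reduce them to ordinary least squares on well-conditioned strata.

The full cohort pipeline (14 packaged subjects × SAL/SAR × 2 / 2.5 / 3.5 m)
runs from one configuration and writes all tables to disk:

```r
run_pipeline(default_run_config(seed = 1), "results_full")
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/shoulderkin.R all --config inst/extdata/smoke_config.yaml --out out
```

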