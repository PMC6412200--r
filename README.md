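# imuhar

Window-level recognition of activities of daily living — sit/stand,
laying, walking, stairs, and transition states — from chest-worn 25 Hz
inertial measurement unit (IMU) recordings of older adults, built to
survive the two inconsistencies uncontrolled deployments produce:
**cross-device baseline shifts** and **mis-oriented sensors**.

It is aimed at researchers analyzing wearable-sensor activity protocols
(and anyone who needs a fully testable reference implementation of this
kind of pipeline): everything runs on a bundled synthetic cohort
generator, so no clinical data are required.

## What it implements

**Feature-based path.** Recordings are cut into 68-sample windows (2.72 s,
50% overlap). Each window yields a pinned 254-feature vector over the
body/gravity acceleration decomposition (zero-phase 0.3 Hz Butterworth),
body jerk, and signal magnitudes, using the classic catalogue of 16 window
statistics (mean, std, MAD, max, min, SMA, energy, IQR, spectral entropy,
AR coefficients, correlations, spectral argmax/mean-frequency/skewness/
kurtosis, FFT band energies). Per-axis feature triplets `(fX, fY, fZ)`
reduce to their 3-D magnitude `sqrt(fX^2 + fY^2 + fZ^2)` (root-sum for
energies, making them exactly rotation invariant), giving a 90-feature
rotation-invariant space. Two class-weighted RBF SVMs — the axis-dependent
model on the Relief-F top-10 features, the rotation-invariant surrogate on
40 — are trained with seeded stratified 4-fold grid search over `(C, γ)`.

Incoming recordings are baseline-harmonized (quiet-segment baselines,
shift-only alignment) and routed by a two-rule orientation detector: a
vertical-axis percentile check, then a 3-D binned Kolmogorov–Smirnov
distance between the recording's raw-value histogram and the training
signatures, thresholded at θ = the maximum within-training pairwise
distance. Predicted label sequences are smoothed with a 4 s moving
majority vote.

**End-to-end path.** Three convolutional network layouts over raw
9-channel windows (1-D temporal convolution with channels in depth; 2-D
over time × sensor; a 12-row "signal image" with stride 1×3), each
conv–batchnorm–ReLU ×3 → dense → softmax with published tuned
hyperparameters, trained by plain SGD — implemented natively in R on BLAS
matrix operations, deterministic under a fixed seed.

**Synthetic cohorts.** A seeded generator emulates the scripted protocol
(standing/sitting/walking 1 min each, stairs 2 × 30 s, laying 30 s) with
posture-oriented gravity, gait oscillations, smooth 5 s transitions, and
ground-truth injection of device rotations and per-axis baseline offsets.

## A worked example

```r
library(imuhar)

cohort <- make_cohort(n_train = 8, n_test = 4, fraction_rotated = 0.5,
                      master_seed = 42)
bundle <- train_bundle(lapply(cohort$train, `[[`, "rec"),
                       lapply(cohort$train, `[[`, "track"), seed = 1)
bundle
#> ModelBundle
#>   axis-dependent: 10 features, C=0.01 gamma=1 (CV acc 85.7%)
#>   rotation-invariant: 40 features, C=10 gamma=0.1 (CV acc 78.4%)
#>   trained on 1576 windows; theta = 0.3184

preds <- list(); truths <- list()
for (s in cohort$test) {
  preds[[s$rec$subject_id]] <- predict_windows(s$rec, bundle)
  truths[[s$rec$subject_id]] <- truth_window_labels(s$rec, s$track)
}
run_evaluate(preds, truths)
#> EvalReport: overall window accuracy 83.12% over 4 subjects
#> confusion matrix (% of actual class):
#>              SIT_STAND LAYING WALKING STAIRS TRANSITION
#>   SIT_STAND      92.07   7.93    0.00   0.00       0.00
#>   LAYING         50.00   0.00    0.00   0.00      50.00
#>   WALKING         0.00   0.00   95.73   3.05       1.22
#>   STAIRS          0.00   0.00    0.00  97.92       2.08
#>   TRANSITION     10.71   2.38    0.00  21.43      65.48
#> routing:
#>  subject_id rule              model  min_dist
#>      test01    2 ROTATION_INVARIANT 0.9081481
#>      test02    1     AXIS_DEPENDENT        NA
#>      test03    2 ROTATION_INVARIANT 1.0000000
#>      test04    1     AXIS_DEPENDENT        NA
```

Reading the output: the two deliberately mis-oriented test subjects were
caught by rule 2 (their raw 3-D histogram distances, 0.91 and 1.00, far
exceed θ = 0.32) and classified with the rotation-invariant surrogate; the
upright subjects passed the vertical-axis check (rule 1) and used the full
axis-dependent model. The cross-validation accuracies show the expected
ordering — the surrogate gives up orientation information, so it trails
the axis-dependent model. Walking and stairs classify almost perfectly;
laying collapses for the rotated subjects because rotation-invariant
features cannot see orientation, which is the only thing separating laying
from sitting; transitions are intrinsically fuzzy, as their windows
straddle two activities.

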