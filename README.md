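# mmhar — multimodal human behavior classification

`mmhar` recognizes whole-body behaviors from two synchronized sensing
modalities: a depth camera delivering a 25-joint skeleton per frame
(Kinect-V2 joint set, ~30 Hz) and four body-worn inertial measurement
units (3-axis gyroscope + 3-axis accelerometer at each elbow and ankle,
~100 Hz). It targets a 10-class behavior vocabulary — baseball pitch
(BP), bat swing (BB), left/right stretch (LS/RS), deep squat (DS),
left/right lunge (LL/RL), normal/abnormal walking (NW/AW), and coffee
pouring (CP) — and is aimed at movement-analysis practitioners who need
a complete, reproducible segmentation → features → classification →
fusion pipeline plus a synthetic data generator to exercise it end to
end.

## The method

**Segmentation.** Each modality yields a difference signal: the distance
between consecutive skeleton centroids,
C_t = ‖c̄_t − c̄_{t−1}‖ with c̄_t = (1/25) Σᵢ j_{t,i}, and the norm of
consecutive-sample differences per gyroscope/accelerometer. Steps
exceeding 5% of each signal's own maximum count as movement; the nine
per-sensor spans are fused by earliest start / latest end.

**Skeleton features.** Per frame, joints are expressed relative to the
right shoulder and normalized by body height h (head to foot-midpoint):
j′_i = (j_i − j_SR)/h. With the body basis S (right→left shoulder),
F (right shoulder→foot midpoint), N = S × F (unit-normalized), the
feature of joint i is (⟨N, j′_i⟩, ⟨F, j′_i⟩, ⟨S, j′_i⟩); stacking
joints and T resampled frames gives a T × 25 × 3 spatio-temporal cube,
flattened to T steps of 75-vectors. These features are invariant to
global translation, rotation, and uniform scaling of the skeleton.

**Inertial features.** The fused segment is cut into M = 6 equal
windows; per window, sensor, and axis the mean μ, population standard
deviation σ, and variance σ² are computed, giving M × 4 × 9 arrays per
channel, flattened to M steps of 36-vectors.

**Classification and fusion.** One classifier per modality: a compact
single-layer LSTM (32 hidden units, dense+sigmoid output of dimension
10, argmax decoding) implemented in compiled code inside the package,
or a linear one-vs-rest SVM baseline on the concatenated features.
The three decisions are fused by majority vote; three-way disagreement
falls back to the largest top-1 score margin. Evaluation is a
stratified 30% hold-out with per-class confusion matrices; the headline
metric is the mean of per-class accuracies.

Because the kind of laboratory recordings this pipeline consumes are
rarely shareable, the package ships a synthetic generator
(`generate_dataset()`) that emulates the study structure: 10 behaviors
× 10 users × 10 repetitions, body heights in 1.29–1.80 m, different
native rates per modality, idle–active–idle recordings with known
ground-truth activity windows, and class-dependent limb motion.

## Worked example

```r
library(mmhar)

# 120 trials: 10 behaviors x 3 users x 4 repetitions
cfg <- generator_config(n_users = 3, n_repetitions = 4, seed = 42)
trials <- generate_dataset(cfg)

# segmentation of one trial recovers the 2-6 s activity window
seg <- segment_trial(trials[[1]])
c(seg$t_start, seg$t_end)
#> [1] 2.01 6.00

# features: 60 x 75 skeleton sequence, 6 x 36 per inertial channel
f <- extract_trial_features(trials[[1]])
vapply(f[c("DEPTH", "GYRO", "ACCEL")], dim, integer(2))
#>      DEPTH GYRO ACCEL
#> [1,]    60    6     6
#> [2,]    75   36    36

# end-to-end evaluation: stratified 30% hold-out, LSTM per modality,
# majority-vote fusion
res <- evaluate_dataset(trials, classifier_config("LSTM", epochs = 60,
                                                  seed = 1), seed = 1)
for (m in c("DEPTH", "GYRO", "ACCEL", "FUSED")) print(res[[m]])
#> <evaluation_report> average accuracy 100.00% (overall 100.00%, n = 40)
#> <evaluation_report> average accuracy 100.00% (overall 100.00%, n = 40)
#> <evaluation_report> average accuracy 90.00% (overall 90.00%, n = 40)
#> <evaluation_report> average accuracy 100.00% (overall 100.00%, n = 40)
```

The four reports carry the per-modality and fused confusion matrices
(`res$FUSED$confusion`), per-class accuracies, and the average accuracy
(mean over classes). The interesting regime is a degraded modality:

```r
noisy <- degrade_modality(trials, "GYRO", extra_noise_sd = 8, seed = 2)
resn <- evaluate_dataset(noisy, classifier_config("LSTM", epochs = 60,
                                                  seed = 1), seed = 1)
round(vapply(c("DEPTH", "GYRO", "ACCEL", "FUSED"),
             function(m) resn[[m]]$average_accuracy, numeric(1)), 1)
#> DEPTH  GYRO ACCEL FUSED
#>  82.5  15.0  80.0  80.0
```

The gyroscope classifier collapses to chance while fusion stays at the
level of the intact modalities — the compensation property that
motivates decision-level fusion. (At this demonstration size, 84
training trials, the wider fused segments caused by the noisy gyroscope
also cost the other modalities some accuracy; on the full 1000-trial
design recomputed by `scripts/acceptance.R`, depth and accelerometer
stay at 100% and fusion compensates completely.)

A thin command-line wrapper over these functions is installed at
`inst/cli/mmhar.R` (`simulate`, `segment`, `featurize`, `evaluate`),
configured by a single YAML file (see `?pipeline_config`).

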