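# actiseg — adaptive-window human activity recognition

`actiseg` recognizes physical activities (walking, running, stair
climbing, sitting, standing, lying) from triaxial accelerometer and
gyroscope streams, for researchers analyzing wearable-sensor recordings —
smartwatch or smartphone IMU data collected in activity studies — where
activity bouts are of **unequal duration** and a fixed analysis window is
always either too short (noisy predictions) or too long (missed bouts).

Instead of fixed windows, the package detects the time points where the
joint distribution of the six channels changes, and classifies each
homogeneous segment.  Segmentation is **greedy Gaussian segmentation**:
with samples $x_1,\dots,x_T \in \mathbb{R}^6$ and breakpoints
$0 = b_0 < b_1 < \dots < b_K < b_{K+1} = T$, the model takes
$x_t \sim \mathcal{N}(\mu_i, \Sigma_i)$ independently within each segment
$[b_i, b_{i+1})$ and maximizes the covariance-regularized log-likelihood

$$\Phi(b) = \sum_{i=0}^{K} \psi_i,\qquad
  \hat\Sigma_i = S_i + \tfrac{\lambda}{n_i} I,$$

by greedy split insertion followed by breakpoint adjustment sweeps.
Around that core the package provides the full pipeline: two-sensor
alignment onto an exact 50 Hz grid, local-line interpolation of missing
samples, long-gap truncation, median + zero-phase Butterworth filtering,
Welch PSD for cutoff selection, signal augmentation (6 → 14 channels) and
a 168-column statistical feature matrix per segmentation, gradient-boosted
tree classification, and per-sample (*instantaneous*) evaluation so that
adaptive and fixed windows are scored on the identical denominator.  A
simulator generates labeled streams with controllable bout structure and
acquisition artifacts (timestamp jitter, inter-sensor offset, missing
spans).

## Worked example

Simulate a wrist-worn-style recording — one session per activity,
subdivided and shuffled into variable-length bouts — then segment it and
extract features:

```r
library(actiseg)
sim <- simulate_activity_stream(breathe_like_protocol(scale = 0.05), seed = 42)
sh  <- shuffle_bouts(sim$stream, sim$labels, n_sub = 10, seed = 43)
sh$stream
#> <sensor_stream> 1650 samples x 6 channels @ 10 Hz nominal
#>   channels: acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z
#>   span: 0..164900 ms

fit <- ggs(sh$stream$channels, K = 59, force_K = TRUE)
fit
#> <ggs_segmentation> K = 59 breakpoints over [0, 1650), lambda = 0.0001499
#>   objective Phi = 5866.6219

F <- segment_features(augment_signals(sh$stream), fit$segments)
dim(F[feature_columns(F)])
#> 60 segments x 168 features
```

The 60 fitted segments line up with the shuffled activity bouts: in this
run, 79% of the 53 true bout boundaries have a fitted breakpoint within
0.5 s — the remainder mostly sit between same-looking static postures.
Feeding the features to the classifier and scoring per sample is wrapped
by `har_benchmark()`, which runs the whole train/test comparison:

```r
har_benchmark("shuffled_bouts", seed = 1)
#>   method size_s accuracy_pct
#>  fixed_w    0.2     86.90909
#>  fixed_w    0.8     89.60606
#>  fixed_w    3.0     77.12121
#>  fixed_w    8.0     61.06061
#>  fixed_w   12.0     50.57576
#>  fixed_w   40.0     32.78788
#>      ggs     NA     91.21212
```

Reading the table: with variable-length bouts, every fixed window size
loses somewhere — 0.2 s windows are too short to see the oscillation
frequencies that distinguish the dynamic activities, while 8–40 s windows
straddle bout boundaries — and the adaptive segmentation (bottom row)
beats the best of them.  On the matching equal-bout condition
(`har_benchmark("equal_bouts", ...)`) a well-chosen fixed window ties or
slightly beats the adaptive method, as expected when there is a single
correct window size.

A thin command-line front end covers the same pipeline for shell use:

```sh
inst/cli/har simulate --profile breathe --scale 0.05 --shuffle-bouts --seed 7 -o exp01/
inst/cli/har segment --in exp01/stream.tsv --method ggs --k 50 -o seg.tsv
inst/cli/har featurize --in exp01/stream.tsv --segments seg.tsv -o features.tsv
```

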