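---
title: "Adaptive windows for human activity recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive windows for human activity recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human activity recognition (HAR) from body-worn accelerometers and
gyroscopes is usually windowed: the stream is cut into fixed-duration
windows, each window is summarized into features, and a classifier labels
each window.  The window size is a compromise.  Short windows track fast
activity changes but produce noisy, unstable label sequences; long windows
stabilize predictions but smear over short bouts.  When activity bouts have
*unequal* durations — the realistic case for free-living wearers, and
especially for children — no single fixed size is right.

`actiseg` implements the adaptive alternative: detect the points where the
joint distribution of the six sensor channels changes, cut the stream
there, and classify each *homogeneous* segment.  Because different
segmentations produce different numbers of windows, all methods are scored
on **instantaneous predictions**: each segment's label is broadcast to
every sample it covers, and accuracy is computed per sample on an
identical denominator.

## The segmentation model

Let $x_1, \dots, x_T \in \mathbb{R}^m$ (here $m = 6$: triaxial
accelerometer and gyroscope).  Given breakpoints
$0 = b_0 < b_1 < \dots < b_K < b_{K+1} = T$, the model assumes
$x_t \sim \mathcal{N}(\mu_i, \Sigma_i)$ independently within each
half-open segment $[b_i, b_{i+1})$.  The fitted criterion is the
covariance-regularized log-likelihood

$$\Phi(b) = \sum_{i=0}^{K} \psi_i, \qquad
  \psi_i = \ell\!\left(x_{b_i..b_{i+1}};\,
           \hat\mu_i,\, \hat\Sigma_i\right),\qquad
  \hat\Sigma_i = S_i + \tfrac{\lambda}{n_i} I,$$

with $S_i$ the biased sample covariance, $n_i$ the segment length, and
$\lambda \ge 0$ a regularization weight.  $\psi_i$ is the full Gaussian
log-likelihood at the plug-in estimates; at $\lambda = 0$ it reduces to
$-\tfrac{n_i}{2}(m\log 2\pi + \log\det S_i + m)$.  The regularizer keeps
short, noisy segments from producing singular covariances and damps
over-splitting.

`ggs()` maximizes $\Phi$ greedily in two phases:

* **Addition** — starting from no interior breakpoints, repeatedly insert
  the single split (over all segments, all admissible positions) with the
  largest gain in $\Phi$.  By default the process stops early when the
  best gain is non-positive; `force_K = TRUE` continues to the requested
  $K$, which is useful when deliberately over-segmenting past the
  model-selection inflection.
* **Adjustment** — sweep the breakpoints in order, re-optimizing each
  within its two flanking segments while the others stay fixed, until a
  full sweep moves nothing.  Every accepted move strictly increases
  $\Phi$ and positions are finite, so termination is guaranteed; the
  `objective_trace` element records the (monotone) objective after every
  accepted move.

For $K = 1$ the greedy search *is* the exhaustive search, which the test
suite exploits: the greedy breakpoint must equal the argmax of a
brute-force scan of `ggs_objective()` over all admissible single splits,
exactly.

`objective_curve()` records $\Phi$ after each addition and suggests the
elbow (the $K$ maximizing the negative second difference).  In practice
one picks a round number somewhat above the elbow, accepting a few
spurious splits in noisy stretches rather than merged bouts.

### Segmentation parameters

| parameter | default | meaning |
|---|---|---|
| `K` | — | interior breakpoints; at prediction time derived from a per-minute rate calibrated on training labels (1.5× the labeled bout rate, i.e. moderate over-segmentation) |
| `lambda` | `1e-3 × median channel variance` | covariance regularization; data-scaled so that the default is unit-free |
| `min_seg_len` | 5 samples | shortest admissible segment; avoids degenerate covariances |
| `force_K` | `FALSE` | insert all `K` splits even at non-positive gain |

Ties among equal-gain splits go to the smallest index, making the fit
deterministic.  Channel order does not affect $\Phi$ (determinant and
trace are invariant under permutation similarity), and at $\lambda = 0$
the breakpoints are invariant to positive per-channel rescaling.
Segmentation consumes the six filtered *original* channels only — the
augmented channels are deterministic transforms of them and would distort
the Gaussian model.

## The processing pipeline

1. **Ingest** (`read_sensor_stream()`, `read_labels()`): delimited text;
   duplicated timestamps are averaged with a warning; label intervals are
   0-based, half-open, validated non-overlapping.
2. **Grid alignment** (`snap_to_grid()`, `align_sensors()`): every sample
   is assigned to the nearest point of an exact 50 Hz grid (period 20 ms,
   anchored at the first sample's floor-to-grid time; halfway ties to the
   earlier point; collisions averaged).  The grid covers each sample's
   nominal sampling period half-open, so an ideal $r$ Hz input occupies
   exactly $T \cdot 50/r$ grid points and the missing fraction is exactly
   $1 - r/50$ — for 10 Hz input, 80% of grid points are missing before
   interpolation.
3. **Interpolation** (`interpolate_missing()`): each missing grid point is
   filled by an ordinary-least-squares line through up to 5 non-missing
   neighbors on each side, evaluated at the missing timestamp; at stream
   edges the available side alone is used.  This generalizes two-point
   linear interpolation while using exactly the stated neighborhoods; the
   operation is idempotent.  Note the estimator is a *local smoother*: its
   neighbor span at 10 Hz is about one second, so content faster than a
   few tenths of a Hz relative to that span is attenuated — acceptable
   here because interpolation precedes a 20 Hz-and-below analysis of
   50 Hz-gridded data.
4. **Gap truncation** (`truncate_gaps()`): runs of *all-channel* missing
   grid points strictly longer than 10 s split the stream; a gap of
   exactly 10.0 s does not.  Per-channel gaps are interpolated, not
   truncated.
5. **Denoising** (`median_filter()`, `butterworth_lowpass()`): a
   width-3 running median removes isolated spikes; a third-order low-pass
   Butterworth (default cutoff 20 Hz) removes high-frequency noise.  The
   filter is applied forward and backward (zero-phase), since the pipeline
   is offline and group delay would misalign features against labels.
   The coefficients come from the standard digital bilinear design, so the
   two-pass amplitude response is
   $1/\bigl(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{6}\bigr)$ — the
   tangent warping matters near Nyquist and the tests assert against this
   (digital) form, not the analog prototype $1/(1+(f/f_c)^6)$.  The
   zero-phase pass itself is implemented in the package (odd extension +
   steady-state initial conditions + a compiled direct-form-II-transposed
   kernel) because the `signal` package's `filtfilt` performs no edge
   handling and visibly distorts stream ends.
6. **Cutoff selection** (`psd_welch()`): Welch power spectral density
   (Hann window, 50% overlap, `nperseg = 256`) supports choosing the
   cutoff by inspection; the estimate is density-scaled so its integral
   approximates channel variance.  A stream at 10 Hz native rate cannot
   be low-passed at 20 Hz (Nyquist is 5 Hz); such profiles use a 4 Hz
   cutoff instead, and the wrapper `preprocess_stream()` skips an
   infeasible cutoff with a warning.

## Features

`augment_signals()` expands 6 channels to 14: the originals, their
time-derivatives (`*_jerk`, central differences over the sample period,
one-sided at edges), and the per-sensor Euclidean norms.
`segment_features()` then computes six statistics — mean, SD, median
absolute deviation (unscaled, about the median), min, max, entropy — per
channel in both domains, giving $6 \times 14 \times 2 = 168$ named
features per segment:

* **Time domain**: the raw segment samples.  Entropy uses the absolute
  values normalized to a probability vector (natural log, zero bins
  contribute 0).
* **Frequency domain**: the one-sided magnitude spectrum of the
  mean-removed segment, DC bin included.  Entropy here is spectral
  entropy.  Segments of different lengths are summarized without
  zero-padding — all six statistics are length-agnostic.

The published feature tradition never pins down "entropy"; the choice
above (signal entropy in time, spectral entropy in frequency) is an
explicit interpretation, tested against its own closed forms.  Two
degenerate-input rules keep the matrix finite: a constant segment has an
all-zero mean-removed spectrum, which scores entropy 0 (the standalone
`shannon_entropy()` still errors on all-zero input, per its contract);
and the DC bin is retained so that even 2-sample segments yield a
spectrum of length ≥ 2, keeping the SD defined.  Segments must hold at
least 2 samples (time-domain SD otherwise undefined).

## Classification and evaluation

Segments are labeled by majority vote over their labeled samples (ties to
the label occurring earliest in the segment; fully unlabeled segments are
dropped from training; purity is retained for diagnostics).  The
classifier is gradient-boosted trees (xgboost, called not re-implemented):
soft-probability multiclass objective, 200 trees, learning rate 0.1, depth
2 (waist-worn profile) or 3 (wrist-worn profile), no subsampling,
single-threaded and seeded so that training is deterministic; rows are
canonicalized by a full lexicographic sort first, so row order cannot leak
into the fit.

`to_instantaneous()` broadcasts segment labels to samples;
`confusion_matrix()` and `summarize_confusion()` score the traces.  Both
per-class diagonal ratios are reported under the neutral names
`row_ratio` (diagonal/row total) and `col_ratio` (diagonal/column total),
because published tables do not always attach the conventional
recall/precision names to the conventional quantities; the package
computes both and lets the reader pick.  Unlabeled truth samples are
excluded from scoring and counted separately.  Ratios with a zero
denominator are `NA`, not 0.

## The simulator

`simulate_activity_stream()` generates the structure the segmentation
model assumes, plus one deliberate violation.  Each activity class is a
stationary 6-channel process

$$x_t = \mu_c + A_c \sin(2\pi f_c t + \phi) + \varepsilon_t,
  \qquad \varepsilon_t \sim \mathcal{N}(0, \Sigma_c),$$

with a random phase per bout and channel.  Static postures
(lying/sitting/standing) have $A_c = 0$ and low noise, with mean vectors
encoding device orientation (units: g, rad/s).  Dynamic activities
(walking/stairs/running) oscillate at gait-like frequencies (1.8, 1.4,
2.8 Hz) with higher noise.  The oscillation intentionally violates the
within-segment i.i.d. assumption — real gait data do too, and the
segmentation must cope.  Class separations are deliberately moderate:
2-sample windows are genuinely ambiguous (the dynamic classes differ
mainly in frequency content, invisible at that length), while long
homogeneous segments separate cleanly.  That is precisely the regime in
which window size matters.

`shuffle_bouts()` implements the variable-bout construction: each labeled
session is split at uniform-random interior cut points into `n_sub`
non-empty subsessions, all subsessions are permuted and concatenated, and
adjacent same-activity subsessions merge in the output labels (so six
10-subsession sessions give 60 subsessions but possibly fewer distinct
bouts).  Per-activity sample counts are conserved exactly.
`degrade_stream()` splits a clean stream into per-sensor files with
timestamp jitter, a constant inter-sensor clock offset, and
non-overlapping missing spans — the artifacts the alignment stage exists
to undo.  With all magnitudes zero the round trip is exact.

What the simulator does **not** emulate: biomechanically realistic gait
harmonics, sensor saturation and drift, postural transitions, or
autocorrelated noise.  Passing tests on this generator therefore
demonstrate the pipeline's correctness and the windowing effect under the
stated model, not field accuracy on any particular device.

## The shipped benchmark

`har_benchmark()` builds a complete synthetic study and runs
`window_size_sweep()` on it, scoring greedy Gaussian segmentation against
fixed windows on identical held-out samples:

* **`shuffled_bouts`** (wrist-worn-like): 14 streams at 10 Hz — per
  stream, one session per activity (five at 60 s plus running at 30 s,
  i.e. 5% of the full 10-minute protocol), subdivided into 10 subsessions
  each, shuffled, concatenated (3300 samples/stream); 12 train / 2 test;
  window sizes 0.2, 0.8, 3, 8, 12, 40 s; depth-3 trees; 4 Hz cutoff.
* **`equal_bouts`** (waist-worn-like): 14 streams at 50 Hz of twelve
  equal 8 s scripted bouts (4800 samples/stream); 12 train / 2 test;
  window sizes 0.2, 0.8, 3, 8 s; depth-2 trees; 20 Hz cutoff.

These desk-scale durations are the package's own choice: they keep a
10-seed, two-condition run in the minutes range on one CPU while
preserving what the comparison is about — the *relative ordering* of
adaptive versus fixed windows, which is driven by bout-length variability
rather than by absolute stream length.  The per-stream breakpoint budget
is `round(1.5 × labeled-bout-rate × duration)` with the bout rate taken
from training labels, mirroring the practice of over-segmenting somewhat
past the objective-curve inflection.  The benchmark runs at the streams'
native rate (both simulated sensors share timestamps, as in waist-worn
phone data); the 50 Hz re-gridding path is exercised separately by the
alignment and degradation tests.

```{r}
library(actiseg)
sw <- har_benchmark("shuffled_bouts", seed = 1)
sw
```

`scripts/acceptance.R` re-runs this benchmark (3 seeds) together with the
pipeline's other checkable quantities and writes them as JSON; the test
suite runs the full 10-seed version.

## Numerical choices, in one place

* Timestamps are integer milliseconds; the 50 Hz grid period is exactly
  20 ms, anchored at the first sample's floor-to-grid time, for
  bit-reproducible grids.
* All indices are 0-based and all intervals half-open `[start, end)`.
* Snap ties (exact halfway) go to the earlier grid point; collisions
  average.  Both rules are order-independent.
* Greedy tie-breaks go to the smallest index.  Adjustment accepts a move
  only on strict improvement beyond a `1e-9` relative tolerance, so
  floating-point noise cannot cycle.
* The returned objective equals `ggs_objective()` recomputed on the
  returned breakpoints to within `1e-9`.
* A final partial fixed window of ≥ 2 samples is kept; a 1-sample
  remainder merges into the last full window, so windows always partition
  `[0, T)`.
* The booster is fixed to `nthread = 1` with an explicit seed; given
  identical features and labels, prediction traces are byte-identical
  across runs.

## Limitations

The greedy segmentation is offline and $O(KT)$ likelihood evaluations per
fit; no warm-start or streaming mode is provided.  $K$ must be supplied
(or derived from a configured rate): the objective curve supports but
does not automate the choice.  The classifier profiles deliberately skip
hyperparameter search.  And the instantaneous-accuracy comparison, while
fair across segmentation schemes, scores boundary samples harshly for
*every* scheme — segment-level accuracies are typically higher.
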