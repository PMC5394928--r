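---
title: "Decoding sound sources and reverberant spaces from simulated MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sound sources and reverberant spaces from simulated MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reverbdecode)
```

## The problem

When a brief impact sound (a hand pat, a pole tap, a bouncing ball) is
played inside a room, the signal reaching the ear is the anechoic source
convolved with the room impulse response (RIR). The reverberant tail carries
information about the enclosing space — larger rooms have longer
reverberation times (RT60, the time for reverberant energy to decay by
60 dB) — while the direct sound carries the identity of the source.
Time-resolved multivariate decoding of MEG sensor patterns can separate the
neural codes of these two scene attributes: source identity is decodable
early and transiently, reverberant-space size later and in a sustained way,
and space decoding follows a stepwise (ordinal) size progression rather than
a mere categorical separation.

`reverbdecode` implements that complete analysis pipeline — preprocessing,
pairwise SVM decoding with trial subaveraging, cross-classification,
temporal generalization, sensorwise maps, sign-permutation cluster
statistics, bootstrap latency confidence intervals, gammatone-cochleogram
stimulus controls, model-RDM comparison and behavioral coupling — together
with a synthetic-data generator that emulates the 3 (source) × 3 (space)
factorial MEG experiment the analysis is designed for. Every stage of the
pipeline is therefore testable end to end without access to any recording.

## The synthetic cohort

`generator_config()` describes a cohort. Its defaults emulate the study
conditions: 14 subjects, 9 conditions, M = 150 trials per condition, 306
sensors in triplets at 102 helmet locations, epochs −200…1000 ms at 1 kHz.
Each trial is

\[
x(t) \;=\; a_s\, g_\text{src}\, k_\text{src}(t)\, \mathbf{S}_{s}
      \;+\; a_r\, g_\text{spc}\, k_\text{spc}(t)\, \mathbf{T}_{r}
      \;+\; \varepsilon(t),
\]

with condition labels \((s, r)\), unit-norm sensor topographies
\(\mathbf{S}, \mathbf{T}\), temporal kernels \(k(t)\), subject-level gain
factors \(g \sim \mathcal N(1, 0.12^2)\), and sensor noise \(\varepsilon\)
that is white Gaussian per sensor plus a rank-5 spatially correlated
component carrying 20% of the variance (rows of the mixing matrix are
normalized so per-sensor variance is exactly `noise_sd^2`). No temporal
autocorrelation is simulated; the 30-Hz low-pass of the preprocessing stage
induces it downstream.

### Temporal kernels

The source kernel is a gamma-shaped transient: rise \(\tau^{a} e^{a(1-\tau)}\)
with shape \(a = 2.6\) and \(\tau = (t - 50)/(130 - 50)\), maximum exactly 1
at 130 ms, multiplied by a half-cosine fade that reaches zero before the
300 ms offset. The shallow shape exponent makes the early rise steep enough
that group-level significance is reached near the target onset (57 ms)
at the default signal-to-noise ratio.

The space kernel is sustained: zero before 130 ms, a half-cosine rise over
the first 15% of the onset–peak interval to a plateau at 0.72, a linear
plateau decay to 0.55, a cosine-squared bump of width ±9% of the peak–offset
interval giving a strict maximum of 1 at 386 ms, and a half-cosine fall that
ends before the 801 ms offset. The bump makes the group-level argmax
well-defined (a smooth plateau would let Monte-Carlo noise move the argmax
by tens of milliseconds); the plateau keeps the kernel at or above half
maximum through 700 ms, which is what produces the broad off-diagonal
temporal-generalization regime and the long significant cluster.

The rise lengths are a compromise with the zero-phase filter: very sharp
kernel edges excite visible ringing of the 30-Hz Butterworth low-pass
(over- and undershoot around transitions), which is harmless for the
argmax but makes the plateau lumpy.

### Topographies

Sensor locations form a Fibonacci lattice on the upper hemisphere; weights
are concentrated over two lateral (temporal-lobe-like) clusters through a
Gaussian angular envelope. An orthonormal basis \(u_1 \ldots u_4\) is drawn
inside the envelope. Source topographies are three exactly equidistant unit
vectors in span\((u_1, u_2)\). Space topographies follow the configured
geometry:

* `"ordinal"` (default): \(\mathbf T_r \propto u_3 + (r-2)\,\gamma u_4\) with
  \(\gamma = 0.5\), normalized — a collinear-plus-offset construction whose
  pattern distances satisfy \(d(1,3) > d(1,2) = d(2,3)\) exactly, so the
  neural RDM inherits a stepwise size progression;
* `"equidistant"`: three mutually equidistant vectors in
  span\((u_3, u_4)\) — the control geometry in which no ordinal structure
  exists.

### Signal-to-noise calibration

The two amplitudes were calibrated once, on the desk-scale configuration,
so that the full pipeline recovers the latency structure the generator
encodes: `snr_source = 0.16` puts the pooled source decoding peak near
80–84% group accuracy, and `snr_space = 0.33` puts pooled space decoding
near 70–72%. A lower space amplitude (peaking near 65%) preserves the
source > space decodability gap equally well but starves the
single-condition (k = 10) analysis of space signal, which makes the
grand-mean decoding peak collapse onto the source peak instead of landing
between the two components (~156 ms); the present calibration keeps all
onsets, peaks and the grand-mean peak simultaneously recoverable without
ceiling effects.

### Problem sizes

The documented desk-scale configuration (`fast = TRUE`: 5-ms sampling, 60
sensors at 20 locations, 10 subjects) is used throughout the test suite and
the acceptance script; full-scale defaults (1 kHz, 306 sensors) are
supported but memory-hungry (≈4 GB per subject). Null-calibration cohorts
use M = 60 trials per condition, and the family-wise-error study uses 200
cohorts with M = 20 and a single subaverage repetition: the permutation
test's error control rests on label exchangeability and does not depend on
M or K, so the smallest configuration that still exercises the whole
decode-then-cluster path is the appropriate one. These sizes are the
package's choices and are stated here so they can be revisited.

### Stimuli and behavior

`synthesize_stimulus()` renders an impact sound as a damped noise burst
(source kinds differ by damping constant and spectral tilt only), convolved
with a synthetic RIR — Gaussian noise with exponential energy decay whose
RT60 equals the requested value, first tap positive (direct path). The
default space set uses RT60 ∈ {0.25, 0.51, 0.68} s. Duration-controlled
stimuli concatenate 10 bursts at 200-ms intervals (a 2000-ms train) before
convolution and ramp the rendered waveform linearly up over the first
second and down over the next, truncating at 2 s.

`generate_behavior_table()` draws, per subject and comparison category
(3 source pairs, 3 space pairs), 36 same–different trials with
gamma-distributed reaction times whose mean follows the latency map and
Bernoulli correctness at the mapped accuracy. The default map couples
reaction time to the component latencies the generator encodes (source
comparisons fast/accurate, space comparisons slow, the most separated pair
within each factor fastest), which is what the behavior–MEG coupling
analysis is designed to detect.

## The decoding pipeline

Preprocessing subtracts the per-trial, per-sensor mean of the −200…0 ms
baseline (half-open at 0) and applies a zero-phase forward–backward
4th-order Butterworth low-pass at 30 Hz. Zero-phase filtering is essential
here: a causal filter would shift every latency estimate.

Decoding follows the subaveraged pairwise scheme: per repetition, the M
trials of each condition are randomly partitioned into ⌊M/k⌋ disjoint
groups of k and averaged into pseudo-trials (leftovers dropped for that
repetition); a linear SVM (C = 1) is evaluated by leave-one-out
cross-validation in which each fold holds out one pseudo-trial per class
jointly; accuracies are averaged over folds, then over K repetitions, then
over condition pairs where applicable. Parameters mirror the emulated
analysis: k = 10, K = 100 for the 9 × 9 RDM; k = 30, K = 300 pooled;
k = 20, K = 150 for cross-classification (training on the 2M trials of two
orthogonal-factor levels, subaveraged within each level separately, testing
on the held-out level; nine combinations averaged). Desk-scale runs reduce
K as stated above.

The SVM dual is solved by a small dense SMO working-set solver on the
precomputed linear Gram matrix (the same optimization problem libsvm
solves; the test suite verifies exact prediction agreement with libsvm via
`e1071` and with a brute-force maximum-margin enumerator on small separable
problems). Decision ties (decision value exactly 0) deterministically go to
the first class. Channels are used in raw units by default; per-channel
z-scoring with training-fold statistics is available
(`decoding_params(scale = "zscore")`) for mixed magnetometer/gradiometer
units, but the generator emits a single homogeneous unit type, so the
default avoids the sevenfold cost of per-fold Gram recomputation.

Degenerate inputs: classes whose features are all identical return chance
(50%) with a warning; a class smaller than k is an error.

## Statistical inference

* **Pointwise test.** One random sign per participant per permutation,
  shared across time points — flipping each time point independently would
  destroy the temporal autocorrelation that cluster inference relies on.
  One-sided p-values use the exact-test convention
  \(p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})\), so
  p = 0 is unattainable.
* **Cluster correction.** Clusters are maximal runs of time points with
  p below 0.05; the statistic is run length in time points; the null is the
  per-permutation maximal cluster size (each permutation's pointwise
  p-values are ranked within the same permutation ensemble); observed
  clusters beyond the 95th percentile are significant. No suprathreshold
  point is a valid outcome (empty cluster list, onset undefined).
* **Latencies.** Onset = first time point of the earliest significant
  cluster; peak = argmax of the group mean within the stimulus window
  (from 0 ms; duration-controlled analyses restrict to 0–2000 ms); ties
  break to the earliest time. Bootstrap CIs resample participants 1000
  times, reusing one fixed sign-flip ensemble across resamples for
  tractability; resamples without a significant cluster contribute no
  onset, and if more than half lack one the onset CI is reported undefined.
* **Maps.** Sensorwise maps use BH-FDR at q = 0.01 across locations per
  time point; temporal-generalization maps use a one-sided one-sample
  t-test against 50% per (train, test) coordinate with BH-FDR at q = 0.05
  over all coordinates; zero-variance coordinates get p = 0 or 1 by the
  sign of their mean.
* **Behavior coupling.** Spearman correlation across the six comparison
  categories between behavioral summaries (gamma-fit mean RT of correct
  different-pair trials; fraction correct) and MEG summaries (per-subject
  peak latency/accuracy of the matching pooled pair course), with CI and
  one-sided p from jointly resampling both participant pools 10,000 times.

## Model RDMs

Conditions are ordered (source, space) lexicographically. The categorical
space model scores 0 for same space level and 1 otherwise; the ordinal
model scores the absolute rank difference (0/1/2); both ignore source
identity. Model–neural correlation is Spearman over the 36 lower-triangle
entries per time point, inside the half-open window [138, 801) ms (the
printed significant-space-decoding window; at 1-ms sampling a closed
interval would contain 664 points, one more than the printed 663, so the
half-open reading is adopted). `compare_models()` pairs the two rho courses
by time point and applies a paired t-test, one-sided (ordinal > categorical)
by default. The direction matters: when the space patterns are equidistant,
the ordinal model's extra 1-versus-2 distinction is pure noise and its rho
is *systematically smaller* by a fixed rank-variance factor
(\(\sqrt{2}/\sqrt{3}\) of the categorical model's group deviation on this
design), so a two-sided test would flag the control cohort; the one-sided
test correctly reports "no ordinal advantage" there.

## Cochleograms

64 4th-order gammatone filters at ERB-spaced center frequencies spanning
20–20,000 Hz (standard cochlear-model defaults; the emulated analysis names
only the filterbank family), applied by FFT convolution to inputs
standardized to exactly 44,100 samples; band energy is summed in 20-ms
windows advancing in 5-ms steps, left-aligned with a zero-padded tail,
yielding exactly 200 bins. Energies below 10⁻²⁰ of the band maximum are
gated to zero so that silent bins are exactly silent. Dissimilarity is
1 − Pearson r between the 64-band energy vectors per bin, averaged over
stimulus pairs; zero-variance bins contribute the no-information value 1.
Pooled curves average the cochleograms within each factor level first and
then correlate across levels, the reading most analogous to the pooled
decoding analysis. Peaks report the bin time (bin index × 5 ms), earliest
bin on ties.

## Numerical choices

* SMO tolerance 10⁻³ on the maximal KKT violation (libsvm's default);
  solutions are warm-started across neighboring time points and
  leave-one-out folds, which changes nothing statistically (verified
  against cold starts) and makes the ~10⁷ small fits tractable.
* Bulk generator noise uses a seeded 64-bit Mersenne Twister with a
  128-layer ziggurat sampler, independent of R's RNG stream; everything is
  a pure function of `(config, subject index)`, and distinct analyses
  derive child seeds from the configuration seed.
* The zero-phase filter uses odd edge reflection; its interior agrees with
  reference implementations to ~10⁻⁷, and edge samples (the first/last few
  of the baseline and epoch tail) differ only in edge-condition convention.

## What passing tests do and do not show

The generator reproduces the statistical *structure* the analysis assumes —
factorial condition labels, two temporally dissociable components with
ordinal space geometry, spatially correlated sensor noise, subject-level
gain variability, gamma reaction times — so green tests demonstrate that
the pipeline recovers known ground truth and that its error rates are
calibrated. They do not certify performance on real recordings, which add
non-Gaussian artifacts, temporally structured noise, between-subject
topography differences, head-position variation and eye/muscle activity,
none of which are simulated. Stimulus synthesis likewise stands in for real
recorded impact sounds and measured RIRs: cochleogram dissimilarity peaks of
the synthetic stimuli are later than the printed ones (which depend on the
unreleased recordings), so only ordering properties, not absolute peak
times, are asserted about them.
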