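# reverbdecode

Time-resolved multivariate decoding of auditory MEG responses in a
3 (impact-sound source) × 3 (reverberant-space size) factorial design, with
a synthetic-data generator that emulates the experiment so the entire
analysis chain can be validated end to end without any recordings.

The scientific question the pipeline addresses: when a brief sound is heard
inside a room, does the brain carry separable, temporally dissociable codes
for *what* made the sound (the source) and *where* it happened (the size of
the reverberant space, cued by the RT60 decay of the room impulse
response)? The package is aimed at auditory/cognitive neuroscientists who
want a tested, reproducible implementation of this decoding methodology —
and at methodologists who want its statistical machinery (sign-permutation
cluster inference, bootstrap latency CIs, representational model
comparison) with calibrated error rates.

## The method

For each time point *t*, trial sensor patterns are subaveraged per
condition into pseudo-trials (random disjoint groups of *k* trials,
averaged), and a linear SVM (C = 1) is scored by leave-one-out
cross-validation on every pair of conditions, holding out one pseudo-trial
per class jointly per fold. Repeating over K random subaverage draws yields
a 9 × 9 decoding RDM per time point (chance 50%). Derived analyses:

* **grand-mean course** — mean of all 36 pairwise accuracies per *t*;
* **pooled decoding** — 3 classes of 3M trials after pooling the orthogonal
  factor (k = 30), the source/space time courses;
* **cross-classification** — train on two levels of the orthogonal factor,
  test on the third (k = 20, nine train/test combinations averaged);
* **sensorwise maps** — the same analysis per sensor triplet (3-channel
  patterns), FDR-corrected across locations;
* **temporal generalization** — train at *t*, test at *t′*.

Group inference: each participant's chance-centered course is multiplied by
a random ±1 per permutation (one flip per participant, shared across time);
clusters are maximal runs of pointwise p < .05, significant when their
length exceeds the 95th percentile of the permutation maximal-cluster-size
null; onset/peak latency CIs come from bootstrapping participants.
Representational geometry is probed by Spearman-correlating the neural RDMs
with a categorical (0/1) versus ordinal (0/1/2) space-size model RDM, and
low-level acoustic confounds by gammatone-cochleogram (64 ERB-spaced bands)
dissimilarity curves of the stimuli.

The synthetic generator embeds a transient source-discriminative component
(onset 50 ms, peak 130 ms) and a sustained space-discriminative component
(onset 130 ms, strict peak 386 ms, ≥ half maximum through 700 ms) in
spatially correlated sensor noise, with exactly ordinal space-pattern
geometry — see the methods vignette
(`vignettes/reverberant-space-decoding.Rmd`) for the model and every
numerical choice.

## Worked example

```r
library(reverbdecode)

cfg <- generator_config(fast = TRUE, n_subjects = 6, seed = 2)
res <- run_experiment1(cfg,
  params_single = decoding_params(k = 10, K = 3),
  params_pooled = decoding_params(k = 30, K = 5),
  params_cross  = decoding_params(k = 20, K = 3),
  infer_cfg = test_config(n_perm = 200, n_boot_latency = 50,
                          n_boot_behavior = 500))

res$pooled$source$inference$onset_ms   # 85
res$pooled$source$inference$peak_ms    # 130
res$pooled$space$inference$onset_ms    # 165
res$pooled$space$inference$peak_ms     # 385
round(res$models$comparison$mean_diff, 3)  # 0.192
round(res$behavior$rt_latency$rho, 3)      # 0.943
```

Reading: even this deliberately small cohort (6 subjects, desk-scale
sampling) recovers the generator's structure — source decoding becomes
significant early and peaks at 130 ms while space decoding rises later and
peaks at 385 ms (the 5-ms grid point nearest the encoded 386 ms); the
ordinal space model fits the neural RDMs better than the categorical one by
Δρ ≈ 0.192; and behavioral reaction times correlate strongly with the
decoding peak latencies across the six comparison categories. Onsets are
conservative at this cohort size (85/165 ms versus the encoded 57/138 ms);
the 14-subject configuration used by the acceptance checks recovers them
within tolerance.

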