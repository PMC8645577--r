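---
title: "Microstate analysis: models, choices and validation"
author: "microstatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Resting-state EEG spends most of its time in one of a small number of
quasi-stable scalp potential configurations — *microstates* — each lasting
roughly 60–120 ms before switching abruptly to another. The analysis
implemented here summarises a multichannel recording by four template
topographies (the canonical classes A–D) and, per subject and class, three
temporal parameters:

* **Duration** — mean length of that class's contiguous segments (ms);
* **Frequency** — number of segments of that class per second of analysed
  time (1/s);
* **Coverage** — fraction of analysed samples labelled with that class.

The per-subject identity `coverage = frequency × duration` holds exactly by
construction (all three derive from the same run counts over the same
denominator) and is asserted on every run. It does *not* survive averaging
across subjects — the mean of a product is not the product of means — so
group-mean tables must not be expected to satisfy it.

The fit quality of a template set is the **global explained variance**
(GEV): the GFP²-weighted mean of the squared spatial correlation between
each topography and its assigned template, where GFP (global field power)
is the spatial standard deviation across channels at one time point.

## Pipeline and its assumptions

1. **Preprocessing** (`preprocess_subject()`): zero-phase 4th-order
   Butterworth band-pass (default 1–40 Hz, applied forward–backward so
   topographies suffer no phase distortion), integer-factor decimation
   (default 1,000 → 500 Hz, preceded by a zero-phase 8th-order Butterworth
   anti-alias low-pass at 0.8 × the new Nyquist), segmentation into
   non-overlapping 2-s epochs (trailing remainder discarded), rejection of
   any epoch whose absolute amplitude reaches 100 µV (`≥` rejects), and
   average referencing. GFP and topographic correlation are only
   reference-invariant under the average reference, which is why it is
   applied unconditionally before microstate computation. Amplitude
   screening operates on the filtered signal. ICA-based artifact correction
   is out of scope — component selection is inherently manual — but
   `epoch_filter` accepts an external keep/drop list so externally cleaned
   or reviewed data slot in.
2. **Clustering** (`modified_kmeans()`): topographies at GFP local maxima
   (moments of highest topographic signal-to-noise) are clustered by the
   microstate variant of K-means. Assignment uses squared spatial
   correlation, so a map and its polarity flip are the same state; the
   cluster prototype is the first eigenvector of the members' cross-product
   matrix, the polarity-invariant analogue of a mean. The objective (GEV
   over the peak maps) is non-decreasing across iterations; the best of 20
   random restarts is kept; K = 4 by default for comparability with the
   bulk of the literature.
3. **Aggregation and ordering**: subject templates are pooled per group and
   re-clustered (`aggregate_group_maps()`), which weighs every subject
   equally regardless of epoch count; group maps are matched to built-in
   idealised A–D references by exhaustive search over all 4! permutations
   (`order_maps_canonical()`).
4. **Backfitting** (`backfit()`, `smooth_labels()`): every sample takes the
   label of its best-correlating template (ties to the lower class index);
   segments shorter than 20 ms are dissolved sample-by-sample into whichever
   flanking segment correlates better. Parameters are computed within
   epochs; a segment never spans an epoch boundary.
5. **Group statistics** (`manova_wilks()`, `posthoc_anova()`): see below.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| band | 1–40 | Hz | conventional microstate analysis band |
| target_srate | 500 | Hz | preserves 1–40 Hz content at ¼ the data volume |
| epoch_seconds | 2 | s | short enough for plentiful artifact-free epochs |
| reject_uv | 100 | µV | amplitude scale separating cortical EEG from gross artifact |
| k | 4 | – | canonical A–D model |
| n_restarts / tol | 20 / 1e-6 | – | restarts against local optima; absolute GEV change |
| smooth_ms | 20 | ms | shortest physiologically credited microstate segment |
| min_corr | 0 | – | every sample assigned; >0 leaves poor fits unlabelled |

## Design choices that were genuinely open

* **GFP²-weighted template updates.** Peak maps can enter the eigen-update
  normalised to unit GFP (every peak equal weight) or raw (weight ∝ GFP²).
  The default is the GFP²-weighting of the GEV objective itself: GFP peaks
  that fall into low-amplitude stretches are mostly noise, and on synthetic
  data with known templates the equal-weight update visibly corrupts the
  class-C template (|r| to truth ≈ 0.6 versus ≥ 0.96 with GFP² weights).
  `normalize = TRUE` restores equal weighting.
* **Smoothing spares epoch-edge segments.** A segment truncated by an epoch
  boundary may be the tail of a genuine state, so its observed length is not
  evidence against it; only interior sub-minimum segments are dissolved.
  Consequently short edge segments can survive smoothing — the one
  documented exception to the minimum-duration guarantee.
* **MANOVA as the multivariate approach to repeated measures.** The
  three-group comparison of a 4-class parameter profile is a mixed design
  (group between subjects, class within). `manova_wilks()` therefore runs
  the one-way MANOVA on the within-subject class-difference contrasts
  (3 columns), whose Wilks Λ, Rao F with df = (6, 68) at N = 39, and
  multivariate η² = 1 − Λ^(1/s) (here s = 2) constitute the group × class
  interaction test; `effect = "profile"` gives the raw 4-column variant,
  df = (8, 66). No covariates are modelled: none are defined for this
  design. Post-hoc one-way ANOVAs per class use df = (g − 1, N − g) —
  (2, 36) for groups of 10/12/17 — with pooled-error pairwise t contrasts
  reported unadjusted and compared against the Bonferroni threshold
  α/(groups × classes) = 0.05/12 ≈ 0.004167.
* **Tie-breaking.** Equal correlations assign to the lower class index;
  smoothing ties go to the left flank; template signs are fixed by making
  the largest-magnitude channel positive. All paths are deterministic given
  a seed.
* **Indices are 1-based**, following R convention, everywhere a sample or
  channel index is exposed.

## The synthetic generator

`make_cohort()` emulates the cohort this pipeline targets: 64-channel
eyes-closed EEG at 1,000 Hz, 30 × 2-s epochs per subject, three groups of
10/12/17 subjects. Microstate dynamics are semi-Markov: the next class is
drawn from a transition matrix with zero diagonal and the dwell time from a
per-class gamma law (shape 4; means 75/85/95/110 ms inside the 60–120 ms
regime). A first-order Markov chain would make dwell times geometric,
which at 500 Hz is nothing like empirical microstate durations, and the
Duration statistic needs controllable ground truth — hence explicit
durations. The scalp signal is `a(t) · map[label(t)] + noise(t)` with
`a(t)` a signed 10 Hz sinusoid (60 µV peak): the topography's polarity
alternates every half-cycle while the map stays fixed, so the GFP traces
the rectified alpha envelope and the signal is zero-mean and entirely
inside the 1–40 Hz analysis band. Noise is spatially smoothed Gaussian
noise (Gaussian kernel over electrode distances, σ = 0.35 head radii) so
that spurious GFP peaks have realistically smooth topographies; it is
scaled to a signal-to-noise RMS ratio of 4. Amplitudes stay well below the
100 µV screen, so generated cohorts pass preprocessing with zero
rejections.

Between-subject variability multiplies each subject's class dwell-time
means by a log-normal factor (sdlog 0.2, mean 1), giving coverage
dispersion of the order seen in resting-state cohorts. The default planted
group effects follow the direction of interest in three-group
epilepsy-versus-control designs: the first group's transition weight into
class A is scaled by 1.8 (raising A frequency and coverage) and its class-C
dwell time by 0.6 (lowering C duration and coverage); classes B and D carry
no effect. Ground-truth parameters are computed from the planted label
sequences by the *same* run-length code (`parameters_from_labels()`) the
analysis uses — one source of truth for the definitions.

What the generator does **not** emulate: interictal discharges, ocular and
muscle artifacts, volume-conducted source mixing, 1/f background spectra,
or non-stationary alpha power. Passing recovery tests on this model shows
the pipeline's numerics are sound under known dynamics; it does not certify
performance on clinical EEG.

## Numerical notes

* Filters are applied forward–backward (`signal::filtfilt`); steady-state
  tests measure mid-recording amplitude to avoid edge transients.
* Empty clusters are re-seeded from the worst-fitting map and logged in the
  iteration trace.
* Degenerate post-hoc inputs (zero within-group variance) are detected
  relative to the data's scale: all-equal data report F = 0, p = 1;
  separated means with zero residual report p = 0 with a message.
* EDF I/O is 16-bit with per-channel symmetric physical ranges; round-trip
  error is at most half a quantisation step.
* Subjects missing a class (Duration undefined) are dropped listwise per
  multivariate test, with a message.

## Problem sizes used in validation

The recovery studies run the full default cohort — 39 subjects × 30 two-s
epochs at 1,000 Hz, SNR 4 — through generation, preprocessing, two-level
clustering and backfitting (about three minutes on one core), recovering
planted group-mean Durations within 10 % relative error, Coverages within
0.05 absolute, and ≥ 90 % samplewise label agreement. Statistical
calibration uses 2,000 null parameter tables (type-I error of the post-hoc
ANOVA against its binomial confidence band) and 200 label-level cohorts
with the default planted effects (classes A and C significant at α = 0.004,
B and D not, in well over 90 % of replicates). Label-level cohorts reuse
the exact generative mechanism and run-length code while skipping EEG
synthesis, which the full-pipeline study already covers.

## Known limitations

* Model order is fixed at the requested K; no selection criteria (KL,
  cross-validation) are provided.
* No transition-syntax analysis, source localisation, or band-resolved
  microstates.
* The canonical reference maps are idealised dipolar patterns on a
  schematic montage; with unusual montages supply your own reference set to
  `order_maps_canonical()`.
* `read_edf()`/`write_edf()` cover plain continuous 16-bit EDF only (no
  EDF+ annotations, uniform sampling across channels).
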