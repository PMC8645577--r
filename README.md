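# microstatr

Resting-state EEG **microstate analysis** for case–control cohorts, in R.

Scalp EEG does not drift smoothly between configurations: its topography
stays quasi-stable for ~60–120 ms at a time, then switches abruptly. These
transient states — *microstates*, conventionally four classes A–D — index
the temporal dynamics of large-scale resting networks, and their statistics
(how long each state lasts, how often it occurs, how much time it owns) are
compared between clinical groups, e.g. epilepsy patients with recent
seizures, seizure-free patients, and healthy controls.

`microstatr` implements the full pipeline:

* **Preprocessing** — zero-phase 1–40 Hz Butterworth band-pass,
  anti-aliased decimation (1,000 → 500 Hz), 2-s epoching, rejection of
  epochs reaching 100 µV, average reference, plus a hook for externally
  reviewed epoch keep/drop lists.
* **Clustering** — topographies at the local maxima of the global field
  power, GFP(t) = spatial SD across channels, are clustered by the
  *modified K-means*: assignment by squared spatial correlation (polarity
  ignored), prototypes updated as the first eigenvector of the members'
  cross-product matrix, best of 20 restarts by global explained variance

  GEV = Σₜ GFP²ₜ · r²ₜ / Σₜ GFP²ₜ.

* **Backfitting** — every sample labelled by its best template, sub-20-ms
  segments dissolved into their flanks, then per subject × class
  **Duration** (ms), **Frequency** (segments/s) and **Coverage** (fraction
  of time), satisfying `coverage = frequency × duration` exactly per
  subject.
* **Group statistics** — Wilks' Λ MANOVA over the class profile (the
  multivariate repeated-measures interaction test, with Rao's F and
  multivariate η² = 1 − Λ^(1/s)), post-hoc one-way ANOVAs per class with
  pooled-error pairwise contrasts against the Bonferroni threshold
  0.05/(3 × 4) ≈ 0.004167.
* **Synthetic cohorts** — a semi-Markov generator (explicit gamma dwell
  times, transition matrix, alpha-modulated signal, spatially correlated
  noise) with complete ground truth, so every stage is testable by
  parameter recovery. Minimal 16-bit EDF read/write is included.

## Worked example

Simulate a small three-group cohort with the default planted effects
(higher class-A occurrence and shorter class-C dwell time in the seizure
group) and run the pipeline end to end:

```r
library(microstatr)
cfg <- generator_config(group_sizes = c(seizure = 4, seizure_free = 4, control = 4),
                        n_epochs = 10, seed = 42)
cohort <- make_cohort(cfg)
res <- microstate_pipeline(cohort$recordings, min_epochs = 10, seed = 7)
print(res)
#> <ms_pipeline> 12 subjects, 3 groups, K = 4
#> mean subject GEV by group:
#>      control      seizure seizure_free
#>       0.9658       0.9658       0.9714

subset(res$summary, parameter == "coverage" & class %in% c("A", "C"))
#>           group class parameter     mean         sd n
#> 25      seizure     A  coverage 0.277100 0.03842942 4
#> 26 seizure_free     A  coverage 0.210725 0.03804641 4
#> 27      control     A  coverage 0.180325 0.01960721 4
#> 31      seizure     C  coverage 0.142075 0.01891584 4
#> 32 seizure_free     C  coverage 0.221725 0.03301438 4
#> 33      control     C  coverage 0.251075 0.03538563 4

posthoc_anova(res$table, "coverage")
#> Post-hoc one-way ANOVA of coverage (Bonferroni alpha = 0.004167)
#>  class          f df1 df2           p
#>      A  8.8825183   2   9 0.007413717
#>      B  2.4353112   2   9 0.142777416
#>      C 14.1387008   2   9 0.001669498
#>      D  0.5516062   2   9 0.594324494
```

The four templates explain ~97 % of the GFP-weighted variance of this
synthetic cohort; the seizure group shows the planted elevation of class-A
coverage (0.28 vs ~0.18–0.21) and depression of class-C coverage (0.14 vs
~0.22–0.25), and the post-hoc ANOVAs (here with df = (2, 9) for 4+4+4
subjects) surface exactly the planted classes. At the default cohort size
(10/12/17 subjects, df = (2, 36)) class A also clears the Bonferroni
threshold.

Real data enter through `read_recording()` (EDF or delimited matrix +
channel sidecar) and `read_cohort()` with a tab-separated manifest of
`subject_id`, `group`, `path`.

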