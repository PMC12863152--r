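# mseeg — resting-state EEG microstate segmentation and group statistics

Resting scalp EEG does not wander smoothly: its spatial configuration stays
quasi-stable for tens of milliseconds and then switches abruptly. These
transient stable topographies — **microstates**, canonically four classes
A–D — index the moment-to-moment activation of large-scale neural networks,
and their temporal statistics (how long each state lasts, how often it
occurs, how states follow one another) are widely used markers of
individual and group differences, for example between socioeconomic-status
groups.

`mseeg` is an R implementation of the standard microstate pipeline for
researchers running such group studies:

* **Segmentation** — global field power
  (GFP, the spatial SD of the average-referenced map) and its peaks;
  polarity-invariant **AAHC** (atomize–agglomerate hierarchical clustering)
  of the peak topographies per participant at fixed *K* = 4; two-level
  group template derivation; optimal-assignment sorting into the canonical
  A–D order; backfitting to a continuous label stream by the nearest-peak
  rule. Fit quality is the global explained variance
  GEV = Σ(GFP·r)² / ΣGFP².
* **Parameters** — per class: duration (ms), occurrence (1/s), coverage
  (fraction), and the segment-level transition matrix P(j | i).
* **Statistics** — SES composite scoring (z-scored parental
  education/occupation), 27 % extreme-group split, Pearson correlations,
  mixed-design repeated-measures ANCOVA (group × class with age/gender
  covariates, Type III, SPSS-style df), Bonferroni post hocs, and
  independent t-tests on transition probabilities.
* **Synthetic ground truth** — a semi-Markov generator of
  resting-state-like 60-channel EEG with known templates, dwell times,
  transition matrix, and programmable group contrasts, so every stage is
  validated by parameter recovery.

## Worked example

Simulate one subject from a known ground truth and fit the model:

```r
library(mseeg)
gt  <- ms_ground_truth(snr = 1)          # canonical A-D maps, 80 ms dwell, 10 Hz carrier
rec <- simulate(gt, seed = 42, duration_s = 20)[[1]]
fit <- microstate(rec, K = 4, band = c(2, 20), sort_against = canonical_atlas())
summary(fit)
```

```
Microstate fit: K=4 classes, 400 GFP peaks, GEV = 94.8%
Templates: A B C D (individual)
GEV per class: A=23.7%, B=22.1%, C=23.4%, D=25.6%

Temporal parameters:
 class n_segments duration_ms occurrence_per_s coverage
     A         60       78.45             3.00   0.2472
     B         66       72.62             3.30   0.2435
     C         67       71.79             3.35   0.2418
     D         65       84.40             3.25   0.2675

Transition probabilities (row = from):
      A     B     C     D
A 0.000 0.414 0.276 0.310
B 0.297 0.000 0.375 0.328
C 0.354 0.292 0.000 0.354
D 0.262 0.361 0.377 0.000
```

Reading this: 400 GFP peaks were clustered; the four fitted maps explain
94.8 % of the GFP-weighted topographic variance. Recovered durations sit
near the generating 80 ms mean dwell, occurrences near the implied
12.5/4 ≈ 3.1 segments/s, coverages near 1/4, and the transition rows near
the generator's uniform 1/3 — the generator's truth, recovered through the
full pipeline. `coef(fit)` returns the template maps, `predict(fit, rec2)`
backfits new data, `plot(fit)` draws the maps, `residuals(fit)` gives
per-peak misfit.

A full group study runs through `microstate_cohort()` (recordings, file
paths, or a generator function; one recording in memory at a time),
`ses_score()` + `extreme_group_split()` for the demographics, and
`ms_group_stats()` for ANCOVAs, post hocs, correlations, and transition
t-tests; `run_microstate_pipeline()` drives all of it from a config and
writes tidy TSV/JSON results. I/O helpers read and write EDF and
delimited-matrix + JSON-sidecar recordings.

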