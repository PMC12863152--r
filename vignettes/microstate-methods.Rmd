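---
title: "EEG microstate segmentation and group statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate segmentation and group statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseeg)
```

## The model

Resting-state scalp EEG shows a striking discreteness: the spatial
configuration of the electric field (the *topography*) stays quasi-stable for
roughly 50–120 ms and then switches abruptly to a different configuration.
These transient stable periods are called **microstates**; four canonical
classes, labelled A–D, recur across individuals and studies and are
interpreted as transient activations of large-scale neural networks
(auditory–language, visual, default-mode, and dorsal-attention networks
respectively).

`mseeg` segments multichannel resting EEG into such microstates and
estimates their temporal statistics. The model underlying the segmentation
is:

* At each time point $t$ the average-referenced map $v(t) \in \mathbb{R}^C$
  is approximately proportional (up to sign) to one of $K$ unit-norm
  template maps $T_1,\dots,T_K$.
* Map strength is measured by the **global field power**
  $\mathrm{GFP}(t) = \sqrt{\tfrac1C\sum_c (v_c(t)-\bar v(t))^2}$, the
  spatial standard deviation of the map. Topographies are most reliable at
  GFP peaks and least defined in GFP troughs, where polarity reversals of
  the underlying oscillations occur; the analysis therefore uses only the
  maps at GFP peaks, and treats a map and its sign-inverse as identical
  (**polarity invariance**).
* Template fit is quantified by the **global explained variance**
  $$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \cdot
  r(v_t, T_{\ell(t)})\big)^2}{\sum_t \mathrm{GFP}_t^2},$$
  the GFP-weighted squared spatial correlation between each peak map and its
  assigned template.

## The pipeline

`microstate()` fits one recording; `microstate_cohort()` runs the standard
two-level group analysis. The stages, each exposed as its own function:

1. **Filtering** (`bandpass`): zero-phase Butterworth band-pass, default
   2–20 Hz, order 4 applied forward and backward with odd reflection
   padding. Epochs (default 2 s) are filtered independently; nothing ever
   crosses an epoch boundary.
2. **Average reference** (`average_reference`): subtracts the spatial mean
   per sample; a projection, hence idempotent.
3. **GFP peaks** (`gfp`, `find_gfp_peaks`): strict interior local maxima,
   plateaus counted once at their first sample, boundary samples excluded.
   No minimum-distance or prominence constraint by default (both available).
4. **Clustering** (`aahc`): atomize–agglomerate hierarchical clustering of
   the peak maps, polarity-invariant, run per participant. Every map starts
   as its own cluster; the cluster contributing least GEV is dissolved and
   its members reassigned independently to the surviving cluster with the
   highest absolute spatial correlation; $K$ is fixed at 4. The cluster
   centroid is the first principal direction of the members' GFP-weighted
   scatter — the polarity-invariant analogue of the mean (plain averaging
   would cancel sign-flipped members). A cluster's GEV contribution is then
   exactly the top eigenvalue of its scatter matrix, which is how the
   compiled core tracks it. Ties (equal contributions, equal correlations)
   go to the lowest cluster index, and input order is fixed, so runs are
   deterministic.
5. **Group templates** (`group_templates`): all individual template maps of
   a group are pooled and re-clustered with the same AAHC at the same $K$
   (uniform weights) — the standard two-level formalisation of "group
   average maps" under polarity invariance. Label-wise principal-direction
   averaging is available as an alternative for pre-sorted sets.
6. **Canonical sorting** (`sort_templates`): group maps are matched to the
   canonical A–D reference atlas by the one-to-one assignment maximising
   total absolute spatial correlation. The assignment is exact (dynamic
   programming over label subsets), not greedy, so it cannot depend on map
   order; each map's sign is then flipped to correlate positively with its
   reference. Individual maps are sorted against *their own group's* sorted
   templates, not the atlas directly — the atlas anchors only the group
   level.
7. **Backfit** (`assign_peaks`, `interpolate_labels`, `backfit`): each GFP
   peak takes the label of its best-correlating sorted template; the
   labels are then expanded to every sample by the nearest-peak rule
   (a sample exactly midway between two peaks goes to the earlier one).
   Labels are categorical, so "interpolating between peaks" can only mean
   this nearest-peak expansion; we state that prominently because the
   phrase is often read as literal interpolation. No temporal smoothing and
   no minimum-duration rejection are applied by default (both opt-in).
8. **Parameters** (`ms_parameters`): per class, mean **duration** (ms),
   **occurrence** (segments per second of labeled time), **coverage**
   (fraction of labeled samples), and the segment-level **transition
   matrix** (ordered within-epoch segment pairs, row-normalised;
   a joint-frequency mode is provided because published "%" transition
   tables are ambiguous between the two conventions).
9. **Statistics** (`ses_score`, `extreme_group_split`, `ms_correlate`,
   `mixed_ancova`, `posthoc_bonferroni`, `transition_ttests`,
   `ms_group_stats`): the socioeconomic-status layer described below.

## Tunable parameters

| Parameter | Default | Meaning / why |
|---|---|---|
| `band` | 2–20 Hz | the conventional microstate band; removes drift and high-frequency noise while keeping alpha dynamics |
| `K` | 4 | the canonical four classes; deliberately fixed, no meta-criterion |
| `polarity_invariant` | `TRUE` | oscillatory fields reverse sign every half cycle; class identity is orientation-free |
| `min_distance`, `min_prominence` | 0 (off) | optional GFP-peak constraints |
| `truncated` | `"exclude"` | epoch-boundary runs have unknown true length; excluding them from the duration mean avoids downward bias. They still count for occurrence and coverage. `"include"` restores the exact identity coverage = occurrence × duration/1000 |
| `transition` mode | `"conditional"` | row-normalised $P(j \mid i)$, matching "probability of transition from one class to another"; `"joint"` also available |
| split `fraction` | 0.27 | the classic extreme-groups tail fraction; `m = ceil(0.27 n)` per tail |

## Handling of degenerate inputs

Flat (zero-variance) maps make spatial correlation undefined: they are
rejected in clustering and left unassigned (with a warning) in backfitting.
Epochs with no GFP peak remain unassigned and contribute no labeled time.
Transition rows with no outgoing segment stay all-zero and are flagged
rather than renormalised. Classes with no counted segment get a missing
duration, not zero. Epochs shorter than the filter's padding are left
unfiltered and counted in a warning.

## The statistics layer

The SES composite averages the two parental education scores (1–5 scale)
and the two parental occupation scores (1–10 scale) into family scores,
z-scores each across the sample (divisor $n-1$), and sums them. The
extreme-group split takes the top and bottom `ceil(0.27 n)` ranked
composites (boundary ties broken by subject id, deterministically, and
reported). With $n = 107$ this yields 29 subjects per group.

Group comparison uses a two-way mixed ANCOVA per parameter family: between
factor group, within factor class, covariates age and gender (coded as a
binary indicator; the convention is unstated in the source literature).
It is computed via the univariate repeated-measures approach with Type III
sums of squares (`car::Anova` under sum-to-zero contrasts), whose error
strata absorb the class-by-covariate terms; with 58 subjects and $K = 4$
this yields the familiar df pattern $F(1, 54)$ between and $F(3, 162)$
within. No sphericity correction is applied, since the convention in the
source literature reports uncorrected df. Partial eta squared is
$SS_{\mathrm{effect}} / (SS_{\mathrm{effect}} + SS_{\mathrm{error}})$
within the stratum. Post hoc per-class group contrasts are
covariate-adjusted ANCOVAs with p-values multiplied by $K$ (capped at 1).
Transition probabilities are compared with pooled-variance independent
t-tests per ordered pair (12 tests for $K=4$), unadjusted by default
(Holm/Bonferroni optional), Welch optional. Pearson correlations between
the SES composite and per-class parameters use the $t$ distribution on
$n - 2$ df. Middle-group subjects are excluded from group contrasts but
can be retained for full-range correlations.

## The synthetic generator

No public recordings accompany the study design this package targets, so
validation is by **parameter recovery** on synthetic EEG with known ground
truth (`ms_ground_truth`, `sample_label_stream`, `render_eeg`,
`simulate_cohort`).

The generative model: segment classes follow a first-order Markov chain
with zero self-transitions; segment lengths follow a geometric law (the
memoryless choice consistent with the first-order view; a gamma law is
optional); the scalp signal is the active class's template times a
sinusoidal carrier, plus spatially white Gaussian noise; the output is
average-referenced. Defaults mirror a typical resting-state regime:
1,000 Hz sampling, 10 Hz carrier, 2-s epochs, 80 ms mean dwell (≈ 12.5
segments/s), uniform off-diagonal transitions, peak GFP 5 µV.

Three design choices deserve emphasis:

* **Signed carrier.** The topography multiplies $\sin(2\pi f t)$, not its
  rectified magnitude. The GFP still traces the rectified envelope (GFP is
  sign-blind), but the field reverses polarity every half cycle — exactly
  the physical reason the analysis is polarity-invariant. A rectified
  envelope would carry most of its energy at DC, which the 2 Hz high-pass
  removes; what survives is a 20 Hz residual whose extrema sit *at* the
  segment switches, so GFP peaks would index transition mixtures and
  recovery would degrade for reasons that have nothing to do with the
  pipeline under test.
* **Carrier-aligned switches** (`align_to_carrier = TRUE`): dwells are
  drawn as whole numbers of half carrier periods (geometric counts, mean
  preserved), so switches fall on carrier zero crossings. This reproduces
  the classic phenomenology — topographies stable around GFP peaks,
  changing during troughs — and guarantees every segment contains at least
  one GFP peak, making ground-truth recovery well-posed. Exact
  sample-resolution dwells remain available (`align_to_carrier = FALSE`)
  for label-stream studies.
* **snr convention**: `snr` is the ratio of time-averaged *broadband*
  signal power to noise power per channel, before filtering. The 2–20 Hz
  band-pass removes most of the white-noise power, so the effective
  post-filter SNR is substantially higher — as it is for real EEG.

Subject-level heterogeneity is modelled by log-normal jitter (default SD
0.1) on dwell means and transition entries (rows renormalised). Group
contrasts enter as multiplicative deltas. `ses_effect_preset(0.3)` encodes
the direction-of-effect pattern reported for low- versus high-status
groups: 30 % longer class-A dwell together with boosted A↔B and A↔D and
damped B↔C and C↔D transition entries. The magnitudes are configurable
because the source literature reports directions, not sizes; note that a
*dwell-only* increase would slightly lower occurrence (occurrence is
$\pi_A / \mathbb{E}[\text{dwell}]$), so the transition component of the
preset is what makes class-A occurrence and coverage rise together, as
observed.

What the generator does **not** emulate: volume-conducted 1/f background,
ocular/muscle artifacts, inter-subject topography variability, bad
channels, or realistic forward head models. Passing recovery tests
therefore shows the pipeline is correct and well-calibrated under the
stated model, not that it is robust to every artifact of real recordings;
artifact handling is assumed done upstream (the documented pass-through).

The montage and the canonical atlas are parametric idealisations defined in
this repository: 60 electrodes placed by 10-10 arc angles on the unit
hemisphere, and A/B/C/D reference maps built from the layout's projected
coordinates $(x, y)$ as $-x + 0.5y$, $x + 0.5y$, $y$, and a fronto-central
Gaussian $\exp(-(x^2 + (y - 0.15)^2)/0.32)$, each average-referenced and
unit-normalised (pairwise $|r| \le 0.68$). Published microstate figures are
images, not numbers, so these coefficients are the package's own; any
user-supplied reference set can replace the atlas.

## Validation studies and problem sizes

The package ships its validation experiments as functions, used by both the
acceptance tests and `scripts/acceptance.R`:

* `transition_recovery_study()`: one 50,000-segment label stream;
  segment-level transition probabilities recovered entrywise (observed max
  error < 0.01 against a non-uniform generator matrix) and per-class dwell
  means within a fraction of a percent.
* `duration_recovery_study(snr)`: the full EEG pipeline — render, filter,
  GFP peaks, per-subject AAHC, group templates, canonical sort, backfit,
  parameters — on a 29+29-subject cohort, 240 s each at 1,000 Hz, without
  subject jitter so the generator's 80 ms dwell is the common truth.
  Recordings are rendered one at a time through a closure, keeping memory
  flat. Cohort-mean durations recover the truth within a few percent at
  snr = ∞ and snr = 1.
* `calibration_study()`: 1,000 two-group null cohorts at the label-stream
  level (29+29 subjects, 60 s streams); Pearson correlation, ANCOVA
  interaction, and transition t-test each reject at the nominal 5 % rate
  within binomial error. The calibration (and the power study) deliberately
  run on label streams rather than rendered EEG: they test the statistics
  layer, and the parameter tables they consume are exactly what the EEG
  path produces after segmentation — whose own fidelity the recovery
  studies establish separately.
* `power_study()`: 200 cohorts carrying the preset 30 % class-A contrast;
  the covariate-adjusted class-A duration contrast is detected (Bonferroni
  p < 0.05, low > high) and the full duration/occurrence/coverage pattern
  reproduced in well over 80 % of replicates.

The study sizes above (60-s calibration streams, 200 power replicates) are
the package's chosen trade-off between Monte-Carlo error and a test suite
that runs in minutes; all are arguments, so larger runs are one call away.

## Known limitations

* AAHC is greedy. On separable inputs with roughly uniform weights it
  attains the exhaustive optimum (verified against full enumeration for
  $n \le 8$), but with strongly uneven GFP weights the lowest-contribution
  victim rule can dissolve a "good" cluster; this is a property of the
  algorithm, not of this implementation.
* The univariate RM-ANCOVA assumes sphericity and applies no correction,
  by design (matching the reporting convention it mirrors); users wanting
  Greenhouse–Geisser df should consult `car::Anova` directly.
* The EDF writer/reader covers continuous 16-bit EDF with a uniform
  sampling rate — the subset this package writes — not EDF+ annotations or
  variable-rate signals.
* Whether peak detection should precede or follow filtering is not settled
  usage; this package filters first (the order implied by the standard
  processing sequence). Epochs are hard boundaries everywhere.
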