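---
title: "Classifying early post-transplant DSA dynamics from few monitoring days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying early post-transplant DSA dynamics from few monitoring days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsamonitor)
```

## The problem

After HLA-incompatible (HLAi) kidney transplantation, donor-specific anti-HLA
antibodies (DSA) are monitored by Luminex single-antigen bead assays, which
report a median fluorescence intensity (MFI) — a semi-quantitative proxy for
antibody level. Within the first 50 post-transplant days, total-DSA
trajectories (the per-time-point sum of a patient's individual DSA MFIs) fall
into a small number of characteristic dynamic patterns:

* **group 0 — no response**: flat, low MFI throughout;
* **group 1 — fast modulation**: a sharp rise peaking around days 10–15 that
  resolves back toward baseline well within the window;
* **group 2 — slow modulation**: a later, broader pulse resolving near the
  end of the window;
* **group 3 — rise to sustained**: starts low, rises, and stays high;
* **group 4 — sustained**: starts high and stays high.

Modulated versus sustained behaviour carries prognostic information for graft
survival, so recognising the pattern early matters clinically. Near-daily
sampling identifies the pattern trivially but is costly; the question this
package addresses is *how few monitoring days suffice to recover the pattern*,
and *which days* those should be.

The classifier is deliberately simple and transparent: each group is
represented by its mean daily trajectory (its *centroid*), both the candidate
series and the centroids are reduced to the same subset of monitoring days,
and a series is assigned to the group whose reduced centroid is nearest in
dynamic time warping (DTW) distance. Performance is summarised by the
classification accuracy

$$C = \frac{N_{cp}}{N_p} \times 100,$$

with $N_{cp}$ the number of correct and $N_p$ the number of all predictions.

## The synthetic cohort generator

The clinical dataset behind this problem is available only on request, so the
package ships a generator (`generate_cohort()`) that emulates its statistical
structure; every downstream stage is exercised on generated cohorts.

### Noiseless shapes

Each group has a parametric mean curve on days $t = 1, \dots, 50$
(`pattern_params()`):

* groups 1–2 use a **gamma pulse**
  $m(t) = b + A\,(t/t_p)^k e^{k(1 - t/t_p)}$ with $k =$ `rise_rate`
  $\times\ t_p$: smooth, non-negative, single-peaked at $t_p$ with maximum
  $b + A$, returning toward baseline $b$. Defaults: $t_p = 12$ with $k = 3$
  (fast modulation; resolved to within 10% of baseline by day 50) and
  $t_p = 18$ with $k = 3$ (slow modulation; resolving near the end of the
  window). The peak days reflect the observed clustering of post-transplant
  DSA peaks within 10–15 days, with the slow pattern lagging.
* group 3 uses a **saturating exponential rise**
  $m(t) = b + (P - b)(1 - e^{-rt})$ from a low baseline ($b = 2000$ MFI) to a
  high plateau, with $r = 0.15$/day (95% of plateau by day 20).
* group 4 **starts high and settles mildly**,
  $m(t) = P + (b - P) e^{-dt}$ with $b = 1.1P$ and $d = 0.05$/day, so the
  max/min ratio over the window stays below 1.2.
* group 0 is constant at its baseline.

The free amplitude ($A$ or $P$) of each group is solved at run time so that
the noiseless curve's mean over days 1–50 equals the average total-DSA level
reported for that group in the reference cohort (`reference_group_mfi()`:
2062, 7023, 7105, 14813, 12674 MFI for groups 0–4). This anchors the
generator's scale to published summary statistics rather than to invented
values; the baselines of the low-starting groups are package choices, since
only the group means are published.

### Noise

Measurement noise is multiplicative lognormal per time point with unit mean
and coefficient of variation `noise_cv` (default 0.15): MFI is positive and
semi-quantitative, with error roughly proportional to level, which makes a
CV-parameterised lognormal the natural model. Within-group parameter
heterogeneity (varying peak day or amplitude between patients of one group)
defaults to *none*: no published values constrain it, so it is exposed
through `pattern_params()` overrides rather than silently assumed.

### Baseline-band mixing

The reference cohort's association between pre-desensitisation MFI and
pattern is encoded in `reference_band_counts()`: DSA counts per pattern in
four baseline bands (<2500, 2500–5000, 5000–10000, >10000 MFI). With
`mfi_band_mixing` enabled, the generator draws a band (marginals proportional
to the band totals), then the pattern from the band's row, then a baseline
uniformly within the band, and rescales the group's default curve to it. The
mixing rows are stored as exact count-derived probabilities — the published
percentage rows are integer-rounded and one row sums to 101 — so that row
sums are exactly 1 and the rounded percentages are still reproduced by
`summarize_bands()`.

### Sampling and preprocessing

The default observation schedule (`default_sampling_schedule()`) mimics
routine practice: daily for two weeks, alternate days to day 28, then sparse
to day 50, always including both endpoints. Preprocessing mirrors the
clinical pipeline: per-DSA series are summed into a total-DSA series
(`sum_dsa()`, interpolating each DSA onto the union of observed days first)
and gaps are filled by linear interpolation onto the daily grid
(`interpolate_daily()`). Outside the observed range the nearest observed
value is extended as a constant — linear extrapolation could produce negative
MFI. Whether the original pipeline interpolated before or after summation is
not documented; both orders are available in `patient_total_daily()`, and
they coincide whenever all of a patient's DSAs share observation days.
Repeated measurements on one day are averaged, the only order-independent
choice.

### What the generator does *not* emulate

Generated cohorts are cleaner than clinical data: no within-group shape
heterogeneity, no assay saturation or batch effects, no missingness beyond
the sampling schedule, no treatment-induced kinks (plasmapheresis, rejection
therapy), and group labels that are true by construction rather than produced
by a clustering step with its own uncertainty. Consequently the accuracies
reported on synthetic cohorts are *upper bounds in spirit*: passing tests
show the pipeline recovers structure it was designed to see, not that a
three-day schedule achieves the same accuracy on real patients.

## The DTW distance

`dtw_distance()` computes the classical unconstrained DTW distance: the
minimum, over all monotone warping paths from $(1,1)$ to $(n,m)$ with steps
$\{(+1,0), (0,+1), (+1,+1)\}$, of the summed local cost $|a_i - b_j|$.
Choices, each exposed as an option rather than hard-wired:

* **local cost**: absolute difference by default; squared difference
  available. Nothing in the problem demands a variant, and the absolute cost
  is robust to the heavy-tailed MFI noise.
* **no warping window**: series are at most 50 points; the full matrix is
  cheap and a band constraint would be an unmotivated extra parameter.
* **no path-length normalisation** by default: series and centroids are
  always reduced to the *same* number of points, where normalisation cannot
  change nearest-centroid rankings.
* **tie-breaking among equal-cost paths** prefers the diagonal step; this
  affects only the reported path, never the distance.

The implementation is a small C++ dynamic program. Its independent oracle,
`dtw_brute_force()`, enumerates every admissible path recursively (no
memoisation, capped at length 8) and is checked against the dynamic program
on hundreds of random sequence pairs in the test suite.

## Classification

`compute_centroids()` takes per-day arithmetic means; `classify()` assigns
the nearest centroid, breaking exact distance ties toward the smallest group
id (a declared, testable rule — ties are rare but real on reduced series).
The classification universe defaults to groups 1–4: the no-response group is
flat and low and in practice identified by inspection, but it can be included
via the `groups` argument.

Evaluation is **resubstitution** by default — centroids are computed from the
same cohort being classified, matching the design of the original analysis —
with a leave-one-out mode (`mode = "loo"`) for honest generalisation
estimates. $N_p$ is always reported alongside $C$, since accuracy
denominators are otherwise easy to misread.

`summarize_bands()` reduces a band-by-group count table to per-band
percentages and broader categories (no response / modulated = 1+2 /
sustained = 3+4). Percentages round **half up** (12.5 → 13), matching the
convention of the published tables; broader percentages are computed from
summed counts *before* rounding, so they are not sums of rounded columns.
A zero-total band yields `NA` percentages and a warning rather than an
error, since real band tables can have empty cells.

## The three-stage day search

**Stage 1 — section sweep** (`sweep_sections()`). Days 1–50 are split into
$N$ contiguous sections and one day is kept per section. The splitting rule
is: first $N - 1$ sections of length $\lfloor 50/N \rfloor$, remainder in the
last section. This is the only rule consistent with the documented behaviour
at $N = 26$ — 25 single-day sections followed by one 25-day section — and
that uneven split is itself scientifically meaningful: it over-represents the
early period, starving the classifier of the late window where slow
modulation separates from the sustained patterns, which is what produces the
characteristic accuracy dip just above $N = 25$. Three selection strategies
are provided: the section's *first* day, its *middle* day (index
$\lceil \ell/2 \rceil$ of a length-$\ell$ section — "middle" is otherwise
undefined for even lengths), or a *random* day per section. The random
strategy repeats (default 100×) with per-repeat seeds spawned from one master
seed and reports the mean, reflecting the clinical reality that sampling days
vary across patients.

**Stage 2 — greedy augmentation** (`greedy_augment()`). Starting from the
2-day schedule found in stage 1 (the first-point strategy at $N = 2$ selects
days {1, 26}), every remaining day is scored as an addition, the best is
kept (ties to the smaller day), and the process repeats up to five days —
mirroring a sequential clinical reasoning process rather than an exhaustive
subset search, which would be feasible but obscures *why* each day is added.
A replacement scan (each kept day swapped against each unused candidate)
guards against a greedy-trapped schedule. Absolute $C$ is reported for every
subset examined, never deltas against a moving baseline.

**Stage 3 — regimen comparison** (`compare_regimens()`). A built-in
catalogue encodes published centre-reported monitoring schedules that fit
within the 50-day window (regimens A–E), alongside the proposed minimal
schedules F = {1, 10, 26} (variant {1, 10, 34}) and G = {1, 10, 26, 34}.
Day lists are encoded literally from their printed sources; regimens
extending beyond day 50 are outside the analysis window by construction and
are rejected at construction time.

`run_full_experiment()` chains all three stages from one configuration (R
list or YAML file) with a single master seed, writes every table plus a JSON
report embedding the configuration and seeds, and is byte-identical across
runs of the same configuration — determinism is asserted in the test suite,
not just promised.

## Problem sizes and numerical choices

The shipped analysis scripts (`analysis/01`–`04`) and the acceptance script
use cohorts of 25 trajectories per group (100 classified series), CV 0.15
noise, and 100 random-strategy repeats — comparable to the 88-patient
reference cohort and large enough that accuracy is reported on a 100-series
denominator. The test suite uses smaller cohorts (2–8 per group) for
structural checks and the full 25-per-group size where an accuracy level is
asserted. Other numerical choices worth knowing: day coordinates are 1-based
integers in [1, 50]; MFI is serialised to CSV with 2 decimal places (Luminex
precision beyond that is not meaningful); all seeds are explicit, and every
stochastic routine restores the caller's RNG state.

## Known limitations

* Synthetic separability: the default shapes are more distinct than real
  patient trajectories; accuracies near 100% on generated cohorts say the
  machinery is correct, not that real cohorts classify that well.
* Resubstitution optimism: the default evaluation re-uses the cohort for
  centroids. Use `mode = "loo"` for generalisation estimates.
* The four-pattern taxonomy is taken as given; the package neither
  re-derives the clustering nor models survival outcomes.
* DTW on very short reduced series (2–4 points) degenerates toward a
  point-wise distance; that is intrinsic to the problem of classifying from
  few days, not an implementation artefact.
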