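---
title: "Quantifying handgrip fatigue and bilateral movement quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying handgrip fatigue and bilateral movement quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguekit)
```

## The measurement problem

Unilateral muscle fatigue is commonly induced with a cued handgrip
protocol: the participant squeezes a dynamometer for 1 s and rests for 1 s,
270 times (9 minutes), holding a target force fixed at 5%, 50% or 75% of
their baseline maximum voluntary contraction (MVC). Fatigue expresses
itself as a decline in what the participant actually produces per
contraction, and — after the task — as a drop in maximal force and altered
movement quality in a bimanual object-hit assessment. This vignette
documents how the package turns those raw recordings into the study's
outcome measures, which choices were genuinely open, and what the bundled
synthetic-data generator does and does not establish.

## MVC: median force between FWHM points

A single maximal squeeze yields a roughly trapezoidal force profile. Peak
force alone is noisy, so the contraction is summarised by the median force
between the profile's full-width-at-half-maximum (FWHM) crossings. Two
details are unavoidable implementation choices:

* **Baseline.** Half-maximum is only meaningful relative to the resting
  force. `fwhm_median()` subtracts the smaller of the medians of the first
  and last 10% of samples. Using the smaller of the two edges protects
  against profiles clipped mid-release; using medians protects against
  spikes.
* **Crossing location.** Half-max crossings are interpolated linearly
  between the bracketing samples, giving sub-sample FWHM times; the median
  itself is taken over the raw samples between the crossings (inclusive),
  because an interpolated median would fabricate values that were never
  measured.

For a best-of-3 MVC block, `mvc_best_of()` keeps the attempt with the
highest median — that winner also defines the fatiguing-task target forces
(5/50/75% of it).

## The fatigue slope

Contraction windows come from the cue schedule, not from a force
threshold: the task is visually prompted, so the cue timeline is the
ground truth of when the participant was supposed to squeeze, and
threshold-based segmentation would silently drop exactly the weak, fatigued
contractions the analysis exists to measure. Each window contributes its
trapezoidal force AUC over the 1 s contraction (raw force, no baseline
correction — the quantity of interest is total produced output). The first
10 contractions are familiarisation and discarded; the fatigue index is
the ordinary-least-squares slope of the remaining 260 AUCs on contraction
number. On exactly linear input the slope is recovered to machine
precision, which the generator exploits (below).

The EMG branch is deliberately the same pipeline applied to a different
carrier: raw EMG is bandpass filtered 10–500 Hz (4th-order Butterworth),
an amplitude envelope is extracted, and the per-contraction envelope AUCs
go through the identical discard-and-regress step. During the assessment
task, where there is no cue structure, the envelope is summarised by its
median over the task window — robust to the sparse large bursts that
reaching movements produce.

Two numerical choices matter here:

* **Zero-phase filtering.** All filters run forward and backward
  (`signal::filtfilt`), so no group delay shifts energy across the 1 s
  window boundaries. The price is a doubled effective order, which is why
  the band-edge contracts below are stated for the round trip.
  Internally the 10–500 Hz bandpass is applied as a high-pass/low-pass
  cascade with the same edges: a single 8-pole bandpass section at these
  normalised frequencies is numerically fragile (its DC rejection
  degrades to a few dB in double precision), while the cascade attenuates
  DC essentially completely.
* **Envelope method.** The magnitude of the analytic signal (Hilbert
  transform, computed by one-sided spectrum doubling) is the default: it
  is parameter-free and tracks amplitude modulation within 2% away from
  edges. A rectify-and-low-pass alternative (6 Hz, 2nd-order, zero-phase)
  is available via `emg_envelope(method = "rectify_lowpass")` for
  comparability with older EMG pipelines; note its steady-state level for
  a tone of amplitude A is 2A/π, not A.

## Kinematic outcomes of the object-hit task

The assessment task logs ball releases (16 bins across a 76 × 44 cm
workspace, 30 balls per bin, 2 per second for 4 minutes, falling at
15–30 cm/s), paddle hits, and both hand trajectories. Four outcomes are
computed per hand: total hits (primary), mean speed, mean absolute
acceleration, and space covered.

* Speed and acceleration use central differences after a zero-phase 10 Hz
  2nd-order low-pass on position; differentiation amplifies sensor noise
  at exactly the frequencies the low-pass removes, and 10 Hz is well above
  voluntary arm-movement bandwidth.
* Space covered is the count of visited 1 cm occupancy cells times the
  cell area. Cells are marked by exact segment rasterisation (all grid-line
  crossings of each inter-sample segment are enumerated), so a hand
  sweeping faster than one cell per sample still paints every crossed
  cell. 1 cm cells on a 76 × 44 cm field give a 3344-cell map — fine
  enough to localise coverage differences, coarse enough that a 4-minute
  trajectory visits a meaningful fraction of the cells it passes.

## Cluster-based permutation test on 2D maps

Comparing space-covered maps cell-by-cell across force levels would
require thousands of correlated tests. The package instead forms clusters
of adjacent suprathreshold cells and tests cluster mass against a
permutation null, which controls the family-wise error while respecting
spatial dependence. The statistic pipeline is: pooled-variance two-sample
t per cell (df = n1 + n2 − 2); a two-sided cluster-forming threshold of
p = 0.01; 4-connectivity components separately for positive and negative
t; a minimum extent of 2 adjacent cells; cluster mass Σ|t|; a null built
from the maximum cluster mass over label reshuffles (5000 by default); and
+1-corrected p-values, so no cluster can ever report p = 0.

Choices that were genuinely open, and why they were resolved this way:

* **Mass vs extent.** Summed |t| (mass) is the common default in
  neuroimaging permutation testing and is sensitive to both broad weak and
  compact strong effects; extent-only statistics are offered by nothing
  downstream, so only mass is implemented.
* **Connectivity.** 4-connectivity is the stricter reading of "adjacent"
  on a grid; diagonal-only contact does not merge clusters.
* **Sidedness.** Positive and negative clusters are formed separately and
  both compared against the same max-|mass| null — a two-sided test at
  overall α = 0.05.
* **Pooled vs Welch.** The pooled-variance t keeps the p = 0.01 → t
  conversion exact under the permutation exchange; Welch is available via
  `pointwise_t_map(welch = TRUE)` for descriptive maps.
* **Paired designs.** The test shuffles rows freely (a two-sample
  design), matching how space-covered comparisons between force levels
  are specified; a within-subject variant would permute condition labels
  within subject pairs and is a possible extension, not a current
  feature.

Calibration is checked empirically: on exchangeable null map sets
(30 × 30 cells, 20 maps per group, i.i.d. standard normal), the fraction
of datasets producing any significant cluster at α = 0.05 must lie in
[0.02, 0.08] across 400 datasets of 1000 permutations each, and an
injected +1.5 SD shift on a 6 × 6 block must be detected — by a
significant cluster covering at least half the block — in at least 90% of
100 replicates. Both checks run in the test suite and in
`scripts/acceptance.R`.

## Within-subject statistics

`rm_anova()` fits the classical univariate repeated-measures
decomposition via `stats::aov` with `Error(subject/(factor))` strata, one
error term per effect, and reports uncorrected degrees of freedom (no
sphericity correction, matching how such designs are conventionally
reported; a Greenhouse–Geisser option was considered and deferred since
nothing downstream consumes it). Partial η² uses each effect's own error
stratum. Exactly degenerate tables (all conditions identical) are reported
as F = 0 rather than 0/0. Follow-up paired t-tests are
Bonferroni-corrected with the family size m (default: the number of
comparisons requested), and Cohen's d is the mean difference over the SD
of differences — the d that corresponds to the paired t via d = t/√n.

## The synthetic-data generator

The generator exists so that every analysis stage has a ground truth.

* **Force sessions** are trapezoidal pulses (0.15 s rise, 0.7 s plateau,
  0.15 s fall — a plausible visually guided grip profile) toward the
  condition target, sampled at 47.75 Hz. The per-contraction amplitude is
  scaled so that the *measured* AUC of each cue window equals
  `A·(on − rise) + β·k` exactly: the generator evaluates the same sample
  grid the segmenter will use, so noiseless recovery of the injected β is
  exact rather than approximate, and any future segmentation bug breaks a
  machine-precision test instead of drifting inside a tolerance.
* **EMG sessions** are band-limited (20–450 Hz) Gaussian noise, unit-SD
  normalised, amplitude-modulated by the contraction gate with a relative
  per-contraction drift, plus a 2% tonic floor; sampled at 2048 Hz. This
  reproduces the amplitude structure the envelope pipeline measures, not
  EMG physiology (no motor-unit statistics, no spectral compression with
  fatigue — so spectral fatigue indices cannot be validated against it).
* **The object-hit simulator** releases balls on a quota-constrained
  shuffled bin sequence (every bin gets exactly its 30 balls, order
  unpredictable) with uniform speeds, and moves each paddle by a
  nearest-threat pursuit policy: target the ball in its own half that
  reaches the defence line (8 cm) soonest, after a 0.2 s reaction delay,
  under a 60 cm/s speed cap, crossing the midline only when its own half
  is empty. Collisions are rectangle–circle tests; hits reflect the
  vertical velocity and add a horizontal component proportional to the
  contact offset. The kinematic stream is 200 Hz — a typical robotic
  manipulandum rate; the policy's speed cap and delay are the "fatigue
  lever" for experiments on the simulator. Paddles do not collide with
  each other.
* **Whole studies** (`simulate_study()`) give every subject all three
  force conditions, with per-condition mean drifts plus a per-subject
  Gaussian jitter (sd 5 × 10⁻⁴ AUC units per contraction). The jitter is
  deliberately identical across conditions — that keeps a zero-drift study
  exchangeable, so the force-level ANOVA's null behaviour can be checked
  without sphericity caveats — and deliberately small: the 5% MVC
  condition produces only ~2.4 AUC units per contraction, which bounds how
  much per-contraction decline any feasible session can carry (a
  condition-scaled jitter was considered and rejected because unequal cell
  variances would themselves inflate the uncorrected F-test's error rate).
* **Spatial map sets** are i.i.d. standard-normal grids with an optional
  mean shift on a rectangular region of one group — the minimal model in
  which the permutation test's size and power have known targets.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible.

What passing on synthetic data does *not* show: robustness to missed or
anticipated contractions (real participants drift off the cue), EMG
artefacts (motion, cross-talk, mains hum beyond the filter band),
trajectory dropouts, or any physiological coupling between the force and
EMG declines. Those require the real recordings; the package's claim is
that, given signals with the protocol's structure, the estimators recover
the truth and the tests hold their error rates.

## Problem sizes used in validation

The test suite and acceptance script run the full protocol sizes where
the quantity is structural (270-cycle sessions at 47.75 Hz, one full
2048 Hz EMG session, the complete 480-ball object-hit simulation) and
Monte-Carlo sizes chosen for stable estimates elsewhere: 50 seeds for
noisy slope recovery, 400 × 1000 permutations for test calibration,
100 replicates for block-detection power, 20 replicate studies for the
end-to-end null. Tolerances follow from the construction: machine
precision where the generator guarantees exactness, 2 Monte-Carlo SEs for
unbiasedness checks, and the stated empirical bands for error rates.

## Known limitations

* Missing samples (NA) are rejected by the analysis operations rather
  than imputed; the protocol's short windows make imputation more
  dangerous than refusal.
* The EMG envelope default (Hilbert) and the rectification alternative
  differ in scale (A vs 2A/π for a tone); slopes are comparable within a
  method, not across methods.
* The simulator's pursuit policy is kinematic, not biomechanical: it
  bounds speed, not force or jerk, so simulated "fatigue" affects hit
  counts and coverage but not acceleration profiles the way real fatigue
  might.
* `rm_anova()` requires complete balanced designs by construction;
  unbalanced data need a mixed-model approach outside this package's
  scope.
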