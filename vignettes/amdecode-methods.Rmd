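---
title: "Decoding true from false autobiographical memories: models and design choices"
author: "amdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding true from false autobiographical memories: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdecode)
```

# The scientific problem

When a person judges whether a sentence describes a detail of their own past
("My wedding dress was white"), does the spatial pattern of brain activity
distinguish details that belong to their autobiographical memory from
plausible but false alternatives? Because autobiographical retrieval is
idiosyncratic — subjects differ in *when* (latency after sentence onset) and
*where* (which voxels) discriminative activity appears — the analysis is
performed entirely within subject, and group-level claims are made about the
spatial *overlap* of the per-subject results, not about averaged activation.

`amdecode` implements that analysis end to end for event-related fMRI with a
true/false trial design: 48 sentence trials (24 true, 24 false) per subject
over 3 runs at TR = 2 s, 14 subjects split into a positive-event group
(wedding, n = 8) and a negative-event group (funeral, n = 6).

# Per-subject decoding model

## Input construction

The voxel time series (assumed already residualized and registered) is
z-scored per voxel **within each run**. Normalizing per run rather than over
the concatenated series prevents run-level offsets from leaking into the
decoder; runs are acquired separately and have no common scale. For each
trial the nine samples at 0, 2, ..., 16 s after sentence onset are
extracted, and a centred three-point moving average produces **seven
overlapping windows** centred 2–14 s post-onset:

$$ w_k = \tfrac{1}{3}\,(y_{2k-2} + y_{2k} + y_{2k+2}), \qquad k = 1,\dots,7 .$$

The 3-point width is the unique choice for which nine samples spanning
0–16 s yield exactly seven windows at 2–14 s; a 5-point average would be
incompatible with that window range.

## Encoding model, voxel selection, pattern matching

At a given window, each voxel's signal is modelled per training set as

$$ y_v = a_v + b_v x + \varepsilon, \qquad x = +1 \text{ (true)},\; -1 \text{ (false)}, $$

by ordinary least squares. The slope $b_v$ measures how strongly the
truthfulness dimension modulates the voxel; the coefficient of determination
$R^2_v$ on the training trials ranks voxels. With an intercept present, the
$\pm 1$ coding is equivalent to 0/1 coding in both $R^2$ and every matching
decision; the symmetric coding is used because it makes the weight sign
interpretable and the two condition predictions symmetric about the
intercept.

Within a **leave-two-stimuli-out** cross-validation (all 24 × 24 = 576
ordered pairs of one true and one false trial; 46 training stimuli per
fold), the model is fitted, the **2,000 voxels** with the highest training
$R^2$ are kept (ties broken by ascending voxel index for determinism), and
clusters of **20 or fewer** face-connected voxels are discarded. The model
then predicts the spatial pattern of each left-out condition
($a_v \pm b_v$), and the fold is scored correct iff the veridical assignment
wins the cosine-similarity match:

$$ \cos(\hat p_T, p_T) + \cos(\hat p_F, p_F) \;>\; \cos(\hat p_T, p_F) + \cos(\hat p_F, p_T). $$

An exact tie is scored incorrect (conservative). A zero-norm vector has
cosine 0 by convention, and a fold whose selection is emptied by the cluster
filter is scored incorrect. Accuracy at a window is the fraction of correct
folds; a bootstrap over fold outcomes (1,000 resamples) gives its standard
error. The subject's **decoding map** at a window is the voxel selection
from a model fitted on all 48 trials — the unique 2,000-voxel set consistent
with treating the map as "the voxels used by the procedure" (per-fold
selections differ only marginally; their union would have no fixed size).
The **best window** is the accuracy argmax, earliest window on ties.

## Significance: the empirical permutation null

The matching procedure's chance level need not sit at 50%: fold outcomes
are strongly dependent (576 folds reuse 48 trials), and shared
trial-to-trial amplitude fluctuations can push whole-window accuracies far
from 0.5 in either direction. Significance is therefore assessed against an
empirical null: **100 label shuffles per window**, pooled across the seven
windows into a common **700-value** reference distribution, and a one-sided
add-one rank test

$$ p = \frac{1 + \#\{a^{null} \ge a^{obs}\}}{1 + N_{null}} . $$

Two implementation details matter for exactness:

* **Full re-decoding per shuffle.** Each null replicate re-runs the entire
  procedure — fold enumeration, training, voxel selection, matching — under
  the shuffled label vector. The null replicate is then the same functional
  of the data as the observed accuracy, so under the no-signal hypothesis
  the two are exchangeable. (Shuffling only the training labels while
  keeping folds and test assignments tied to the real labels produces a
  null with the right mean but a smaller variance than the observed
  cross-validated statistic, and Monte-Carlo runs showed it rejects far too
  often.)
* **Shuffling within runs.** Per-run normalization jointly standardizes the
  trials of a run (they share the estimated run mean and SD), so the
  transformation that leaves the data distribution invariant is relabelling
  within runs. Within-run shuffles also preserve per-run class counts.

One shuffle is drawn per replicate and reused across all 576 folds,
preserving the dependence structure among folds. Draws are independent
across windows. No multiplicity correction is applied across the seven
windows or across subjects; the calibration tests account for the
seven-window multiplicity by checking the pooled subject-window rejection
rate.

# Group-level analyses

## Posterior probability map

Taking each subject's decoding map at their best window, the group map
records per voxel the fraction of subjects whose map contains it. The
display threshold **p > 0.33** keeps voxels informative in **at least 5 of
14** subjects; face-connected clusters of fewer than 20 voxels are dropped
(non-strict at 20 here, unlike the strictly-greater-than-20 rule inside the
decoder: the group-map rule is a minimum cluster size of 20). The cluster
table reports size, centre of mass and the peak-probability voxel in grid
coordinates; anatomical labelling is out of scope.

## Sparseness permutation test

If the discriminative regions are stable across subjects, combining maps at
the *best* windows should concentrate probability mass — fewer
suprathreshold voxels — compared with combining maps at *random* windows.
Each of 10,000 iterations draws one window uniformly per subject, rebuilds
the probability map, and records the total voxel count at every threshold
k/n (k = 1..n); the observed combination is tested one-sided (low counts =
high overlap) with the add-one rule, pointwise per threshold. The seven
fixed-window combinations (all subjects at the same window) are evaluated
against the same null for reference.

Two boundary behaviours are worth knowing. If every subject's map were
identical at every window the test is degenerate (observed = null, p = 1) —
the "ideal map" limit. Less obviously, if the selection budget (2,000)
coincides exactly with the true informative extent and every informative
voxel is recovered, the observed best-window maps become identical across
subjects and the observed count at moderate thresholds sits *inside or
above* the null rather than below it: random-window draws still pick the
true map once per seven draws but scatter otherwise, thinning high-overlap
counts. The regime that actually mirrors partially-overlapping group maps
(real group maps peak well below full overlap) is a selection budget
*larger* than the informative extent, so the acceptance checks exercise the
sparseness property on a cohort with 1,000 informative voxels under the
procedure's fixed 2,000-voxel selection.

## Valence comparison

Timing: the per-subject best windows of the two groups are compared with an
exact-enumeration Mann-Whitney U test (mid-rank ties, two-tailed by
doubling the smaller tail, capped at 1). With groups of 8 and 6, all
C(14, 6) = 3,003 assignments are enumerated; the implementation is verified
against a brute-force oracle and, on tie-free data, against the exact
`wilcox.test`.

Topography: the Sørensen-Dice coefficient
$SD(A,B) = 2|A \cap B| / (|A| + |B|)$ is computed between all pairs of
best-window maps, and the ratio

$$ R = \frac{\text{mean within-group } SD}{\text{mean between-group } SD} $$

is tested against a permutation distribution obtained by shuffling group
labels (preserving the 8/6 sizes; 10,000 iterations). Maps are declared
group-specific iff the observed R falls outside the empirical 2.5–97.5
percentile interval. Percentile (not pivot) intervals are used, with the
interval bounds taken as the order statistics at the add-one positions
`floor(0.025 (n+1))` and `n + 1 - floor(0.025 (n+1))` — the same exact
finite-sample convention as the add-one rank test, under which an
exchangeable observed R is covered with probability at least 95%
(interpolated quantiles of the raw draws are measurably anticonservative
at moderate n). The calibration test checks ≥ 93% coverage across 500
seeded cohorts.

# The synthetic cohort generator

No raw data accompany the study design, so the package ships a seeded
generator producing cohorts with the statistical structure the analysis
assumes:

* **Geometry.** A 20×20×20 grid; the gray-matter mask is the central ball
  covering 70% of the grid (~5,600 voxels). The informative voxels
  (default 2,000) are planted as a few contiguous blobs of ≥ 21 voxels —
  large enough to pass the cluster filter — and are drawn **once per
  cohort**: all subjects share the same informative regions, which is
  precisely the premise the sparseness test probes. Latency, labels and
  noise vary per subject.
* **Noise.** AR(1) Gaussian per voxel (lag-1 correlation 0.3, unit
  stationary variance), independent across voxels. The value 0.3 is a
  typical residual autocorrelation after prewhitening; its exact value only
  mildly affects the effective noise of the 3-point windows. Spatial noise
  correlation is omitted — sufficient to exercise temporal smoothing and
  permutation calibration, but see the caveats below.
* **Condition signal.** The generator emits trial-locked normalized
  response directly (no hemodynamic convolution: the analysis operates on
  residualized, normalized signal, so HRF shape is irrelevant to the
  decoder's contract). Because the 3-point smoothing maps 9 raw samples to
  7 windows, the raw 9-TR amplitude profile is solved (minimum-norm) so
  that the smoothed response equals ± effectSize/2 at the subject's latency
  window and exactly zero at the other six. The planted effect is thereby
  confined to one analysis window — the true-minus-false difference at that
  window is `effectSize` noise SDs — which makes best-window recovery
  well-defined and keeps off-latency windows at chance.
* **Trial-level variability.** A per-trial amplitude fluctuation shared
  across informative voxels (window-scale SD `trialSd`, default 1, injected
  independently per TR) bounds decoding accuracy away from 100%: with
  thousands of informative voxels the independent voxel noise averages out
  of the pattern match, and without a shared trial-level component every
  subject would saturate at ceiling accuracy across several windows. With
  effectSize = 2 and trialSd = 1, peak accuracies land in the 80–95% range
  with off-peak windows near chance — the qualitative shape real
  per-subject accuracy profiles show.
* **Trial layout.** Onsets every 18 s within runs (4 s lead-in, ≥ 18 s
  tail), so 0–16 s extraction windows never overlap; labels are balanced
  within runs. All randomness derives from `(seed, subject index)` through
  fixed substreams, so cohorts are bit-reproducible and adding one
  consumer of randomness does not perturb the others.

What the generator does **not** emulate: spatially correlated noise,
motion and physiological artifacts, hemodynamic dispersion differences,
trial exclusions, or between-subject anatomical variability. Passing tests
on synthetic cohorts therefore demonstrate the correctness and calibration
of the *procedure*, not expected effect sizes on real data.

# Numerical and design choices

* **Cluster connectivity** is face (6-neighbour) by default, the most
  conservative standard choice; 18 and 26 are available. Components are
  labelled by a vectorised union-find over hashed neighbour pairs and
  verified against a brute-force BFS oracle in the tests.
* **Cluster-size rules** differ deliberately between stages: the decoder
  drops clusters of size ≤ 20 (strictly larger than 20 survives); the
  group map keeps clusters of size ≥ 20 (a 20-voxel cluster is reportable).
* **Ties**: voxel-ranking ties break by ascending linear index; accuracy
  ties across windows resolve to the earliest window; a cosine-match tie is
  incorrect.
* **Degenerate inputs**: zero-variance voxels are zeroed with a warning and
  carry zero weight and zero R²; empty selections score their fold
  incorrect; two empty maps have Dice 0; a between-group mean Dice of 0
  makes R an error rather than infinity.
* **Observed sparseness combination**: the best-*accuracy* window per
  subject (the Methods-style definition), not the lowest-sparseness
  combination; the null band is pointwise per threshold.
* **Problem sizes in the checks.** The test-suite Monte-Carlo runs use the
  full 20³ grid where the property concerns the study geometry (parameter
  recovery, sparseness), and reduced subjects (8³ grid, ~200 mask voxels,
  16 trials) where the property is distributional (type-I calibration, null
  size), with permutation counts of 30–100 per window and 500–1,000
  group-test iterations. The acceptance script's end-to-end cohort runs 14
  subjects on a 10³ grid with 24 trials, 100 informative voxels and a
  200-voxel selection budget (the partial-overlap regime discussed above).
  These sizes were chosen so the whole validation remains comfortably
  reproducible on a laptop while every statistical property under test is
  still well-powered.

# Known limitations

* The exactness argument for the permutation null relies on per-run
  normalization and trial exchangeability within run; designs with strong
  slow drifts inside a run (not modelled here, as input data are assumed
  residualized) would weaken it.
* The sparseness test's direction at a given threshold depends on the
  relation between the selection budget and the true informative extent
  (see above); interpreting it on real data requires the full threshold
  sweep, not a single threshold.
* Exact Mann-Whitney enumeration is limited to about 200,000 assignments;
  larger groups fall back to a tie-corrected normal approximation with a
  message.
* Cluster geometry is reported in voxel-grid coordinates; mapping to world
  space is the caller's responsibility via the NIfTI affine.
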