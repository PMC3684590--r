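---
title: "Methods: connectivity MVPA for functional dyspepsia"
author: "dysconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity MVPA for functional dyspepsia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it implements, the
choices that were genuinely open, and what the synthetic tests do and do not
establish.

## The model

The pipeline treats case-control discrimination on whole-brain resting-state
connectivity as a fitted model with three nested layers.

**Connectome features.** Each subject contributes a T×R ROI time-series
matrix (reference acquisition: 6-minute sessions at TR = 2 s give 180
volumes; the first 10 are conventionally discarded). Columns are linearly
detrended and band-pass filtered to 0.01–0.08 Hz. The default filter is an
ideal frequency-domain mask: the stated specification is a rectangular band,
the mask realizes it exactly on the DFT grid, and a zero-phase 4th-order
Butterworth (`method = "butterworth"`) is available for users who prefer a
realizable IIR response. Nuisance signals (white matter, CSF, ventricles,
motion summaries) enter as a caller-supplied T×K regressor matrix — the
composition of that matrix varies across labs and scanners, so the package
deliberately pushes it to configuration rather than hard-coding one reading;
global signal regression is intentionally absent. Features are
`atanh(r)` for every ROI pair, vectorized row-major over the strict upper
triangle (R(R−1)/2 features; 523776 at R = 1024). Correlations with
|r| ≥ 1−1e−12 are clipped with a warning rather than erroring: degenerate
duplicated signals occur in synthetic data and in pathological real inputs,
and a finite feature with a warning preserves the pipeline's shape.

**Fold-wise selection.** Inside leave-one-out cross-validation, each fold's
training set is tested edge-wise with a pooled-variance two-sample t-test.
Pooled variance (rather than Welch) is a deliberate choice: with the group
labels permuted, the fold's total sum of squares is invariant, so the t²
statistic is a monotone function of the squared group-mean difference. Two
consequences follow. First, ranking observed p-values within the permutation
null — the retention rule, keep iff rank/(B+1) ≤ P — is exactly a
permutation test on |t|, which resolves an ambiguity in how "significance of
the distribution" may be operationalized: the rule is stated, tested, and
has the attainable retention floor(P·(B+1))/(B+1) under the null. Second,
the permutation pass needs only the permuted patient-group sums, i.e. a
single matrix product of the 0/1 assignment matrix with the feature matrix;
the Rcpp/Armadillo kernel batches all folds' permutations into such products
and processes edges in blocks, which is what makes 40 folds × 200
permutations × 4005 edges interactive (≈0.4 s) on one core.

One label shuffle per iteration is shared across all edges, preserving the
edges' dependence structure; permutation seeds derive deterministically from
(master seed, fold id), so any single fold can be reproduced in isolation.
Edges with zero pooled variance are silently non-significant inside folds
(an error would abort an otherwise valid fold on a degenerate edge).

The second filter keeps edges whose Pearson correlation with the training
patients' NDI-QoL is two-sidedly significant at `corr_alpha`. The level of
this filter is not pinned by the reference analysis; 0.05 is the default and
it is exposed as a parameter. The fold's subset is the intersection of the
two masks.

**Stabilization and classification.** With M the number of folds (of N)
retaining an edge, edges with recurrence M/N ≥ τ form the stable subset
(τ swept over 1.00, 0.95, 0.90, 0.85; τ = 1 is the consensus set, and the
retained set grows weakly as τ falls or P rises — a tested invariant).
Classification is a linear SVM with C = 1 on features standardized by
training-fold statistics: with edges ≫ subjects a linear margin is the
defensible default, and kernel/C are configurable rather than tuned. In
`feature_mode = "stable"` the stable set is recomputed for every outer fold
from an inner leave-one-out over the training subjects only — whether the
original stable-set classification reused one global set (which leaks the
held-out subject into selection) is not decidable from its description, so
the leak-free variant is the default and the global variant is available,
labeled, via `stable_scope = "global"`. Folds with empty feature sets fall
back to the training majority class and are logged. Accuracy significance
uses label shuffles of the *entire* pipeline (selection included), with
`perm_p = (1 + #{null ≥ real})/(1 + n_shuffles)` so p is never zero.

**Severity.** Out-of-fold NDI-QoL predictions for patients come from
leave-one-out epsilon-insensitive linear SVR on the stable edges — the
reference analysis names the prediction family but not the scheme, and
out-of-fold prediction was chosen over in-sample because the CSI is meant to
generalize; both the kernel and the scheme are arguments. CSI_i =
pred_i / mean(pred), so mean(CSI) = 1 is a hard invariant. Partial
correlations are computed from the inverse correlation matrix with p-values
on n−2−k degrees of freedom; the test suite checks them against explicit
double residualization, and the per-edge QoL correlation controlling age is
implemented by that residualization route directly.

**Network report.** Node weights count stable-edge incidences (handshake
identity tested); connection lengths are Euclidean distances between
centroids, in a single millimetre convention declared by the atlas and never
converted; the QoL-correlation sign splits edges (an exact zero — measure
zero on continuous data — classifies as positive, a documented tie-break);
per-system tallies count an edge once for each system it touches.

## The synthetic cohort generator

The generator defines the study conditions under which everything is tested.

* **Clinical scores.** Truncated normals with the reference cohort's
  group-wise means/SDs (patients: NDI-QoL 76.65 ± 10.17, symptom
  47.2 ± 15.87, SDS 44.4 ± 10.0, SAS 42.6 ± 7.2, duration 37.8 ± 28.2
  months; controls: 87.41 ± 5.44, 1.23 ± 1.90, 33.9 ± 5.8, 32.3 ± 5.9). A
  latent severity factor with loadings (QoL −0.6, symptom 0.8, SDS 0.55,
  SAS 0.55) induces the observed correlation pattern — QoL tied to symptom
  burden, symptom tied to depression/anxiety — while duration is drawn
  independently, reproducing its reported unrelatedness.
* **Planted edges.** Ten abnormal edges by default, each with a
  patient-minus-control Fisher-z shift of 2 noise-SDs (noise SD 0.25, a
  plausible between-subject edge variability) and a within-patient QoL
  coupling targeting |r| = 0.65, 65% of them negative. The correlation
  target was fixed a priori by power reasoning: at ~19 training patients the
  correlation filter passes r = 0.65 with probability ≈ 0.93 per fold, which
  is what makes a recurrence threshold of 0.90 meaningful — strong enough to
  recover, not so strong that the filter never bites. The reference analysis
  reports no effect sizes for the real abnormal connections, so these are
  explicit tuning choices of the test bench, not estimates.
* **Time series.** Optionally, band-limited unit-variance latent signals are
  pairwise mixed to realize each subject's planted correlation, then
  contaminated with linear drift, an out-of-band 0.15 Hz tone and white
  noise, so conditioning is genuinely exercised. Planted pairs must be
  vertex-disjoint (mixing is pairwise). Edge-level generation is the default
  test path; the time-series path exists to test conditioning, not to model
  hemodynamics.

What passing tests show: the selection machinery is calibrated under the
null (retention ≈ floor(P·(B+1))/(B+1); label-shuffle significance uniform),
recovers planted structure at the stated effect sizes, and the arithmetic
identities (CSI mean, confusion-count accuracy, handshake, AUC) hold
exactly. What they do not show: performance on real scans, where effect
sizes, autocorrelation, motion artifacts and site effects are unknown; the
across-subject QoL-correlation signs in the generator are dominated by the
group contrast (patients are shifted *and* have lower QoL), so sign-split
analyses are exercised within patients, where the planted slopes govern.

## Numerical and scale choices

* Desk scale is R = 90 (4005 edges), 20+20 subjects, 200 permutations per
  fold — the full 1024-region, 1000-permutation configuration is supported
  (the kernel chunks edges), but the smaller scale exercises every code path
  while keeping the complete test suite, including twenty end-to-end
  label-shuffle calibrations at 50 shuffles each, in the tens of minutes on
  one core. Shuffle counts below the reference 1000 are a calibration-run
  economy, not a change to the method; the permutation-p resolution floor
  (1/51 here) stays below the 0.05 decision level.
* CSV artifacts round numerics to 10 significant digits before writing;
  identical configurations therefore reproduce byte-identical run
  directories (a tested property).
* ROI and edge indices are 1-based throughout, the natural convention in R.
* Rank-deficient nuisance designs warn and fall back to a pseudo-inverse
  fit rather than erroring, since all-zero regressor columns are a common
  degenerate configuration.

## Known limitations

No spatial preprocessing (slice timing, realignment, normalization,
voxel-to-ROI averaging) is implemented — inputs begin at ROI time series.
The generator does not model hemodynamics, spatial autocorrelation or
motion; atlas centroids are uniform in a brain-sized box, so connection
lengths are realistic only in scale. Replication-cohort evaluation assumes
the same feature space (same parcellation) as the original cohort.
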