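---
title: "Supercell statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supercell statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(supercell)
```

## The problem

Multiparameter single-cell measurements — multicolor flow cytometry panels,
automated nuclear morphometry, single-cell expression — are heterogeneous:
the within-class cell-to-cell spread is typically much larger than the
between-class mean difference, so individual cells from a healthy and a
diseased sample occupy heavily overlapping regions of measurement space. A
classifier trained on single cells therefore hovers near chance, and an
unsupervised projection (SVD/PCA) picks variance-maximizing axes that have
no reason to align with the class difference. At the same time, classifying
patients by a single summary vector (e.g. the per-patient mean) throws away
the cloud structure and leaves a patient-level classifier with as few
training points as there are patients.

This package implements the middle road: **supercell statistics**.

## The model

A *supercell of size N* is the arithmetic mean of the measurement vectors of
N randomly selected cells from one sample. Drawing K such supercells
represents the patient as a point cloud of K points in measurement space.
If the cells are draws from a distribution with finite per-measurement mean
and variance, the central limit theorem gives supercell marginals that are

* narrower by a factor of about $1/\sqrt{N}$, and
* closer to Gaussian as $N$ grows,

regardless of the shape of the single-cell distribution. Overlapping
single-cell class distributions therefore pull apart: for a 1-D class mean
difference $\delta$ and within-class SD $\sigma$, the midpoint rule
classifies a supercell correctly with probability
$\Phi(\sqrt{N}\,\delta / 2\sigma)$ — the closed form exposed as
`expected_accuracy_1d()` and used throughout the tests as an independent
oracle. At $\delta/\sigma = 1$, single cells top out at
$\Phi(0.5) \approx 0.69$ while supercells of 30 reach
$\Phi(2.74) \approx 0.997$.

Supercells are classified with a soft-margin linear SVM, which for
separable input is the max-margin perceptron. The components of the unit
normal to the hyperplane — the *perceptron amplitudes* — are computed in
z-scored space, so a component's absolute value measures that measurement's
relative contribution to the class separation independently of its raw
units, and its sign says which class the measurement is elevated in.
Sorting by absolute amplitude (`rank_measurements()`) yields the
most-to-least-relevant measurement order; refitting on the top M and
sweeping both N and M (`accuracy_grid()`) maps the tradeoff between cells
averaged and markers measured.

Patient-level prediction uses a leave-one-patient-out jackknife
(`jackknife_predict()`): the boundary is trained on every other patient's
supercells and the held-out patient's own cloud of K supercells is read
off. A patient is called for a class only when at least a fraction
$\theta$ of the cloud falls on that class's side; clouds cut by the
boundary are *unclassified* rather than forced. Cohort outcomes are
reported as percentages of patients correct / unclassified / incorrect,
which always total 100.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `size_n` | — | Cells averaged per supercell. The quantity of interest; sweep it. |
| `count_k` | 100 | Supercells per sample. 100 gives the abstention rule a 1%-resolution cloud without dominating run time. |
| `replacement` | `"never"` | Cells are distinct within one supercell; different supercells are drawn independently and may overlap. Disjoint partitioning would cap K at cells/N, which contradicts treating the cloud as repeated random re-draws, so it is not offered. |
| `threshold` ($\theta$) | 0.95 | Abstention threshold on the cloud fraction. The comparison is `>=`, so a cloud exactly at $\theta$ is classified; values $\le 0.5$ are rejected because both classes could qualify. |
| `m_values` | all prefixes | Numbers of top-ranked measurements to sweep. |
| `ranking_scope` | `"per_fold"` | Recompute the ranking inside each jackknife fold so no information from the held-out patient leaks into marker selection. `"global"` reproduces a single cohort-wide ranking. |
| `margin_cost` (C) | 1000 | Effectively hard-margin on separable supercells, while still converging on overlapping single-cell input. Lower values (1–10) are useful when fitting large overlapping single-cell sets, where the hinge solution is the quantity of interest and hard margins are meaningless. |
| `evaluation` | `"held_out"` | `accuracy_grid()` splits each sample's *cells* in half before building supercells, so no cell contributes to both fitting and evaluation. `"training"` evaluates on the training supercells themselves. |

Standardization is fitted on the training supercells at the working N.
Zero-variance measurements cannot be z-scored and are dropped with a
warning (recorded in the boundary's `dropped` field). Ranking ties are
broken by input column order, so results are reproducible.

## Randomness and reproducibility

Every randomised operation derives its own RNG stream from the master seed
plus a stable string hash of identifying tags (sample id, supercell
geometry, the purpose of the draw). Consequences worth knowing:

* identical seed + config + data give bitwise-identical results, including
  the entire jackknife summary;
* adding a patient to a cohort does not change any other patient's
  supercells;
* each test patient's K supercells are built once and reused across all M
  within a fold (and across folds), so accuracy-versus-M curves differ only
  by measure set, not by sampling noise;
* the caller's `.Random.seed` is saved and restored around every internal
  draw.

## The synthetic generator

`synthetic_spec()` / `generate_cohort()` emulate the statistical regime the
method is designed for: two classes of patients whose per-measurement mean
difference $\delta_i$ is small relative to the within-class cell SD
$\sigma_i$ (non-separable single cells), additive patient-level random mean
offsets (what makes leave-one-patient-out nontrivial), uninformative
measurements ($\delta_i = 0$), optional per-measurement skew (a
standardized log-normal transform — flow intensities are rarely symmetric),
and optional shared subpopulation structure (a mixture of component mean
offsets, for studying the multimodality caveat below).

What it deliberately does **not** emulate: spectral spillover,
autofluorescence, doublets, acquisition drift, patient-specific covariance
structure, or class-specific subpopulation frequencies. Passing tests on
generated cohorts therefore demonstrate the statistical mechanics of the
method — narrowing, ranking, abstention, sample-size tradeoffs — not
robustness to cytometry artifacts, which belongs to upstream preprocessing.

## Numerical choices

* **Classification rule.** A supercell is on the positive side iff its
  signed distance is $> 0$; a point exactly on the hyperplane counts as
  negative. The first class in `cohort$class_names` maps to the positive
  side.
* **Orientation.** The SVM backend's internal sign convention depends on
  data order; the boundary is re-oriented from the reported decision
  values so that `positive_class` is always on the positive side.
* **No finite-population correction.** Width ratios are compared to the
  plain $1/\sqrt{N}$; drawing 30 of 10,000 cells without replacement
  shrinks the variance by under 0.3%, far below Monte-Carlo noise at the
  validation sizes used.
* **Text round-trip.** `write_cell_table()` prints doubles with 17
  significant digits, so write-then-read reproduces a cohort bit for bit.
* **Degenerate inputs.** Non-finite cells, duplicate measurement names,
  empty gates, single-class training labels, zero single-cell SD in
  `width_ratio()`, and folds that lose a class are all hard errors naming
  the offending sample/measurement; "criterion never met" in
  `minimal_measures()` / `minimal_supercell_size()` is a reported `NA`
  with `achieved = FALSE`, not an exception.

## Validation design and problem sizes

The test suite builds every fixture in code. Choices a reader may want to
know about:

* The grid-versus-closed-form comparison uses one patient per class with
  40,000 cells and K = 1000 supercells. With K comparable to the number of
  cells, supercells share source cells and are positively correlated, and a
  binomial SE on the evaluated fraction understates the true Monte-Carlo
  error; a large pool with a modest K keeps the clouds effectively
  independent so the 3-SE comparison is honest.
* The max-margin fit is checked against an exhaustive search over all
  2-point and 3-point candidate boundaries on small 2-D separable sets —
  exact for such sets — to $10^{-6}$ margin units.
* Rank-order stability is asserted as a trend: over six fixed generator
  seeds, the mean Spearman correlation between rankings at N = 200 and
  N = 500 exceeds the mean between N = 1 and N = 500 on skewed, overlapping
  cohorts. Per-seed orderings fluctuate — that fluctuation at small N is
  the phenomenon itself.
* The "exactly three markers needed" case is pinned by construction:
  class-A patient means are coordinate permutations of (1,1,0) and class-B
  of (0,0,1), so classes separate in the 3-D signal subspace but collide in
  every 1- and 2-D projection.
* Quantitative checks on the published progeria and uveitis cohorts are
  implemented end to end but require the publicly archived cohort tables
  (see `tests/testthat/test-acceptance.R` for the expected layout); without
  those files that one test reports a failure naming them.

## Known limitations

* Two classes only; multiclass differential diagnosis is out of scope.
* If single-cell distributions are strongly multimodal because of
  well-defined subpopulations, averaging mixes the modes and can discard
  the discriminating structure; the bimodal-generator test shows
  small-supercell accuracy collapsing to chance where a unimodal cohort of
  equal total variance retains signal. Gate to subpopulations first
  (`gate_subpopulation()`), then build supercells within each.
* Amplitudes are linear weights in z-scored space; they rank measurements
  for a linear boundary and say nothing about nonlinear marker
  interactions.
* Gating thresholds are user-supplied; there is no automatic threshold
  inference, compensation, or intensity transform.
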