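---
title: "Tract-wise normative T1 deviation mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-wise normative T1 deviation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Quantitative T1 relaxation times (ms) are sensitive to demyelination,
iron accumulation and axonal loss, both inside focal multiple-sclerosis
lesions and in normal-appearing white matter (NAWM).  `tractnorm`
implements a tract-wise analysis of T1 deviations: a voxel-wise
normative model learned from healthy subjects assigns every patient
voxel a z-score, z-scores are aggregated over atlas-defined white-matter
tract masks split into lesion and NAWM compartments, and the resulting
tract metrics are correlated with current disability (EDSS at baseline,
EDSS0) and disability evolution over ~2 years (ΔEDSS).  Differences
between dependent correlations are tested by permutation and corrected
across tracts with Benjamini–Hochberg (BH).

All stages assume their inputs live on one common template grid; the
package refuses mixed grids rather than resampling, because inter-subject
registration is a separate concern handled upstream of this analysis.

# The normative model

At each brain voxel $v$ the expected T1 of a healthy subject with
covariates (age, sex) is

$$E\{T1\}(v) = \beta_0(v) + \beta_{sex}(v)\,\mathrm{sex}
 + \beta_{age}(v)\,a + \beta_{age^2}(v)\,a^2,$$

with $a = \mathrm{age} - \bar{\mathrm{age}}$ centered at the healthy
cohort's mean age and sex coded 1 = male, 0 = female.  `fit_normative_model()`
solves this by ordinary least squares independently at every voxel (one
shared QR decomposition of the $n \times 4$ design applied to all
voxels), with no spatial regularisation.  The residual SD is
$\hat\sigma(v) = \sqrt{RSS(v)/(n-4)}$ — the unbiased choice under the
4-parameter model; the estimator is this package's decision, since
homoscedastic OLS admits several conventions.  $\hat\sigma$ is floored
at `sigma_floor` (default 1 ms) to avoid division blow-ups in degenerate
synthetic data; the floor is logged whenever applied.

Patient deviation maps are
$z(v) = (T1(v) - E\{T1\}(v))/\hat\sigma(v)$, NaN outside the brain
mask.  Lesional voxels are *not* excluded at this stage: compartment
metrics are read out separately later.  With $n = 92$ training subjects
the held-out z distribution is slightly super-unit
(SD $\approx \sqrt{(n-4)/(n-6)} \approx 1.01$, plus coefficient
estimation error); the calibration tests allow SD in $[0.90, 1.10]$.

A cohort of at least 5 subjects is required (4 coefficients + 1 df for
the variance); rank-deficient designs (all-male cohorts, a single
common age) are refused naming the degenerate covariate.

# Tract masks

Streamline density maps (voxel-wise streamline counts from a
tractography atlas) become binary tract masks through a fixed order of
operations: **merge** left/right hemispheric maps by voxel-wise
summation, **normalize** by the maximum, **binarize** at 5% of the peak.
The order matters — normalizing before merging would inflate the weaker
hemisphere — and a test pins a case where the two orders differ.  The
threshold comparison is inclusive (≥); binarization at 5% of a
Gaussian-profile tube of width $s$ retains the analytic radius
$s\sqrt{2\ln 20} \approx 2.45\,s$, which the tests verify within one
voxel.  Tract masks are intersected with the normative brain mask so
NaN z-scores never enter summaries.  Midline tracts pass through the
merge as identities.

# Compartment metrics

For each patient and tract, the lesion mask splits the tract into
disjoint compartments (`nawm = tract ∧ ¬lesion`,
`lesion = tract ∧ lesion`), and three biomarkers are extracted per
compartment:

* $\mu_{|z|}$ — mean absolute z-score, the *magnitude* of deviation;
* $V_{|z|>2}$ — the number of voxels with $|z|$ **strictly** greater
  than 2, the *spatial extent* of deviation (also emitted in mL, since
  voxel counts are not comparable across anisotropic grids);
* LV — lesion volume on the tract in mL (1 mL = 1000 mm³).

Globally, TLV (total lesion volume) and TLC (lesion count as connected
components under 26-connectivity — faces, edges and corners connect;
the connectivity is configurable and pinned by a flood-fill oracle
test) are computed per patient.  Conventions worth stating: mask
binarizations (lesion concentration, tract density) use inclusive ≥,
the abnormality count uses strict >, and empty compartments yield
missing values — never zeros — so that sparsely lesioned tracts drop
out of pairwise-complete correlations rather than biasing them.  The
lesion-concentration threshold defaults to 0.5.

# Registration QC

Mutual information between each registered anatomical image and the
template is computed from a 2D joint histogram (64 equal-width bins per
axis by default, natural logarithm; both are configurable).  The
flagging threshold is the fifth percentile of MI over the whole MS
cohort jointly, with linear interpolation between order statistics;
subjects strictly below it are flagged for visual inspection.  The
small-sample positive bias of histogram MI is about
$(b-1)^2/(2n)$ nats, negligible at $10^5$ voxels and 16–64 bins; tests
require independent-noise MI below 0.02 nats.

# Statistics

Spearman correlations (Pearson on average ranks, pairwise-complete)
relate each tract metric to EDSS0 and ΔEDSS.  Correlation *magnitudes*
are compared with permutation tests (default $N = 5000$) that
randomize the order of the EDSS scores across patients:

* magnitude vs extent: $|c(\mu_{|z|}, \cdot)| - |c(V_{|z|>2}, \cdot)|$,
  two-sided, in NAWM and lesions;
* z-metrics vs lesion load: $|c(\mu_{|z|}, \cdot)| - |c(LV, \cdot)|$,
  one-sided (alternative: the z-metric correlates more strongly);
* current vs future disability: $|c(X, EDSS_0)| - |c(X, \Delta EDSS)|$,
  two-sided, for $X \in \{\mu_{|z|}^{NAWM}, \mu_{|z|}^{lesions}, LV\}$.

In the two-outcome comparison a *single shared permutation* reorders
both outcome vectors, preserving the EDSS0–ΔEDSS dependence while
breaking the metric–outcome link.  P-values use the add-one estimator
$(1 + \#\{d^* \ge d_{obs}\})/(N+1)$, so they are never 0; BH correction
is applied across tracts *within* each hypothesis family, not pooled
over families.  Per-test permutation seeds are derived deterministically
from one master seed.  Tracts lesioned in fewer than `min_patients`
(default 5; the threshold is a free parameter since no canonical value
exists) patients are excluded from lesion-compartment families.  The
Wilcoxon rank-sum test used for cohort-table comparisons enumerates all
assignments exactly for combined $n \le 12$ (ties included) and uses a
tie-corrected normal approximation otherwise.

# The synthetic study generator

No patient data ship with the package, so `simulate_study()` generates
a full study with known ground truth.  What it emulates:

* **Cohorts**: 92 healthy (age 37.3 ± 10.6 y, 63% female), 47 early-MS
  (31.8 ± 8.0 y, 75% female), 52 progressive (49.9 ± 7.2 y, 65% female);
  ages from truncated normals on [18, 75] — outside the healthy age span
  the quadratic model extrapolates poorly, so the generator stays inside
  it.  Follow-up intervals 24.7 ± 1.3 (early) and 25.0 ± 3.7 months.
* **Geometry**: an ellipsoidal brain on a 24³ grid (1 mm isotropic by
  default), smooth low-order polynomial coefficient fields (baseline T1
  ≈ 850–950 ms, σ ≈ 30–38 ms), and Gaussian-profile tube tracts: CST
  (projection, left+right — exercising hemispheric merging), corpus
  callosum (commissural, midline), inferior cerebellar peduncle
  (cerebellar, left+right) and medial lemniscus (brainstem) — two
  supratentorial and two infratentorial bundles.  On grids below ~24³
  the tube tails of supra- and infratentorial tracts overlap and
  compartments cross-contaminate; 24³ is the smallest comfortable
  default.
* **Damage**: each patient draws a latent per-tract severity
  (Gamma(2, 2), mean 1).  Diffuse NAWM T1 elevation adds
  `nawm_effect` (60 ms) × severity × density profile on each tract;
  focal ellipsoidal lesions (+300 ms, recorded in the lesion mask) are
  seeded on tract centerlines with probability proportional to density
  and severity, biased 3:1 toward supratentorial tracts (where MS
  lesions predominate), with a 20% off-tract fraction so that
  ΣLV ≠ TLV cases are exercised.
* **Outcomes**: EDSS0 is a monotone function of mean *supratentorial*
  severity plus Gaussian noise (per-cohort intercepts 0.7/4.0 — the
  progressive cohort starts far higher on the scale); ΔEDSS is a
  monotone function of mean *infratentorial* severity plus noise.  Both
  are snapped to the half-point grid and clipped to [0, 10], and the
  follow-up score is reconstructed so that ΔEDSS is always
  `followup − baseline`.  The noise SDs (0.6 and 0.45) were chosen once
  so that tract–EDSS Spearman correlations land in a realistic 0.2–0.4
  range at n ≈ 47–200; effect sizes of NAWM damage are free parameters
  of the generator, not estimates of any real cohort.

What it does **not** emulate: MR physics (bias fields, B1, the MP2RAGE
signal equation), mis-registration, spatially correlated noise (an
optional smoothed-noise mode exists as a stress test), anatomical
variability of tracts, and lesion pathophysiology.  Passing tests
therefore show the *pipeline arithmetic and inference* are correct and
calibrated under the generator's assumptions — not that the biological
conclusions transfer to any particular scanner or cohort.

# Numerical choices and degenerate inputs

* Voxel-wise OLS via one shared QR; agreement with an independent
  scaled-normal-equations solver is tested at 1e-8.
* σ floored at 1 ms; z maps NaN outside the brain mask; NaN voxels are
  excluded from (not propagated into) compartment summaries.
* Constant images in the MI histogram degenerate to a single bin with a
  warning rather than an error.
* All-zero tract densities are refused ("empty tract"); the peak voxel
  always survives binarization, so masks are never empty.
* Permutation tests error on constant metric vectors (Spearman
  undefined); the study driver skips such tracts and reports the rest.
* Determinism: every stochastic step takes a seed; the pipeline derives
  per-test seeds from one master seed, and rerunning a configuration
  reproduces every output byte-identically.

# Problem sizes used in the shipped checks

The validation suite runs the study conditions at phantom scale: the
normative recovery and z-calibration checks use n = 92 on a 16³ grid
(~1,400 brain voxels, pooled held-out z over ≥10⁵ voxels); analytic
null checks of $\mu_{|z|}$ and $V_{|z|>2}$ use 10⁶ standard-normal
voxels; permutation validity uses 500 replicate datasets of n = 47 with
1000 permutations each; the end-to-end ranking experiment uses 50
replicate studies of 200 early-MS-like patients on the 24³ default
grid with a permuted-outcome negative control.  These sizes were chosen
as the smallest at which the sampling-theory predictions are sharp
enough to be discriminating.

# Known limitations

* The tract atlas shipped for tests is synthetic tube geometry; real
  tractography atlases (e.g. HCP-derived density maps) are supported as
  input via `load_tract_atlas()` but not bundled.
* The normative fit assumes homoscedastic Gaussian residuals per voxel;
  heavy-tailed inter-subject variation would miscalibrate z tails.
* V|z|>2 counts depend on voxel size; use the mL variant across grids.
* ΔEDSS on an ordinal scale is a coarse progression measure; the
  generator's monotone link is a convenience, not a clinical model.
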