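# tractnorm

Tract-wise normative T1 mapping and disability correlation analysis for
quantitative MRI studies of multiple sclerosis.

## What it does, and for whom

Radiological lesion counts explain disability in MS only partially;
microstructural tissue changes — measurable as prolonged T1 relaxation
times — occur both inside lesions and in normal-appearing white matter
(NAWM), and *where* they sit in the white-matter wiring matters.
`tractnorm` is for imaging researchers who have co-registered
quantitative T1 maps, lesion masks and a tract atlas on a common
template grid and want to:

1. fit a **voxel-wise normative T1 model** on a healthy cohort,

   E{T1}(v) = β₀(v) + β_sex(v)·sex + β_age(v)·a + β_age²(v)·a²,

   with a = age − mean cohort age, sex ∈ {0 = F, 1 = M};
2. map each patient's deviations as **z-scores**
   z(v) = (T1(v) − E{T1}(v)) / σ̂(v), with σ̂ the per-voxel residual SD;
3. aggregate z over **binary tract masks** (hemisphere-merged,
   max-normalized, binarized at 5% of peak streamline density), split
   into **lesion** and **NAWM** compartments: μ|z| (mean |z|,
   magnitude of deviation), V|z|>2 (voxels with |z| strictly > 2,
   spatial extent), tract lesion volume LV, plus global TLV/TLC;
4. flag poorly registered datasets by **mutual information** against
   the template (fifth-percentile rule over the MS cohort);
5. correlate metrics with disability (Spearman, EDSS0 and 2-year
   ΔEDSS) and compare correlation magnitudes with **permutation tests**
   (N = 5000, outcome order randomized across patients) under seven
   null-hypothesis families, **Benjamini–Hochberg**-corrected across
   tracts within each family.

A fully synthetic study generator (healthy + early + progressive
cohorts with known ground-truth damage and EDSS links) stands in for
clinical data, so the entire pipeline is testable offline.

## Worked example

```r
library(tractnorm)

cfg <- pipeline_config(
  sim = sim_config(n_healthy = 40, n_early = 30, n_progressive = 30,
                   seed = 42),
  n_perm = 1000, min_patients = 3, seed = 42)
res <- run_pipeline(cfg, "demo_run")

print(res$model)
#> Voxel-wise normative T1 model
#>   trained on n = 40 subjects, age centered at 39.0 y
#>   4896 brain voxels (24x24x24 grid), sigma floor 1 ms (0 voxel(s) floored)

print(res$metrics)
#> Tract metric table: 60 patients x 4 tracts (240 rows)
#>   TLV 0.14 +/- 0.06 mL, TLC 5.1 +/- 1.8

print(res$study)
#> Correlation study: 88 correlations, 56 permutation comparisons (n_perm = 1000)
#>   BH-significant comparisons at alpha = 0.05: 10
#>       cohort                 family tract     d_obs      p_perm       p_adj
#>  progressive          mu_nawm_vs_lv   CST 0.5430231 0.000999001 0.003996004
#>  progressive          mu_nawm_vs_lv    CC 0.5292255 0.001998002 0.003996004
#>  ...
```

Reading the output: each comparison row tests a difference of absolute
Spearman correlations.  `mu_nawm_vs_lv / CST, d_obs = 0.54` says that in
this synthetic run the NAWM mean-|z| of the cortico-spinal tract
correlated more strongly with baseline EDSS than the tract's lesion
volume did (one-sided permutation p = 0.001, BH-adjusted 0.004 across
the four tracts) — exactly the kind of signal the generator injects, as
diffuse NAWM damage drives the synthetic outcomes alongside focal
lesions.  `run_pipeline()` also writes the dataset, fitted model (NIfTI
+ JSON), metric CSVs, QC table, correlation/comparison CSVs, a JSON
manifest of every stage's parameters and a plain-text report into the
run directory; rerunning the same config reproduces them byte-for-byte.

Individual stages are exported too: `fit_normative_model()`,
`zscore_map()`, `build_tract_masks()`, `build_metric_table()`,
`qc_cohort()`, `run_correlation_study()`, and the generator functions
(`generate_ground_truth()`, `simulate_healthy_cohort()`,
`simulate_patient()`, `simulate_study()`).  A thin CLI wrapper lives at
`inst/cli/tractnorm.R`.

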