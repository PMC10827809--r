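Package: tractnorm
Title: Tract-Wise Normative T1 Mapping and Disability Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a voxel-wise normative atlas of quantitative T1
    relaxation times from a healthy cohort, maps patient-specific T1
    deviations as z-scores, aggregates deviations over atlas-derived
    white-matter tract masks split into lesion and normal-appearing
    white matter (NAWM) compartments, and relates the resulting tract
    metrics to current and future disability (EDSS) via Spearman
    correlations compared with permutation tests and Benjamini-Hochberg
    correction.  Includes a synthetic-study generator producing healthy
    and patient cohorts with known ground truth, registration quality
    control based on mutual information, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
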