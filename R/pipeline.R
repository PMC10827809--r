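# End-to-end pipeline driver:
# simulate -> fit atlas -> z-scores -> tract masks -> metrics -> QC -> stats.

#' Pipeline configuration
#'
#' Collects every threshold and seed of the pipeline in one place.
#' Defaults: tract density threshold 0.05, |z| cutoff 2, lesion
#' concentration threshold 0.5, 26-connectivity, 5000 permutations, QC at
#' the fifth MI percentile with 64 bins, sigma floor 1 ms.
#'
#' @param sim a [sim_config()] describing the synthetic study (or `NULL`
#'   when running on an existing on-disk dataset).
#' @param density_threshold tract binarization fraction of peak density.
#' @param z_threshold absolute z cutoff for the extent metric.
#' @param lesion_conc_threshold lesion concentration binarization cutoff.
#' @param connectivity lesion-count connectivity (6, 18 or 26).
#' @param n_perm permutations per comparison.
#' @param min_patients lesion-support cutoff for lesion-compartment
#'   analyses.
#' @param bh_alpha BH significance level for reporting.
#' @param qc_bins,qc_percentile MI histogram bins and flagging percentile.
#' @param sigma_floor residual-SD floor (ms).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), density_threshold = 0.05,
                            z_threshold = 2, lesion_conc_threshold = 0.5,
                            connectivity = 26, n_perm = 5000,
                            min_patients = 5, bh_alpha = 0.05,
                            qc_bins = 64, qc_percentile = 5,
                            sigma_floor = 1, seed = 1L) {
  stopifnot(density_threshold > 0, density_threshold <= 1,
            z_threshold >= 0, lesion_conc_threshold > 0,
            lesion_conc_threshold < 1, connectivity %in% c(6, 18, 26),
            n_perm >= 1, qc_bins >= 2,
            qc_percentile > 0, qc_percentile < 100, sigma_floor > 0)
  structure(list(sim = sim, density_threshold = density_threshold,
                 z_threshold = z_threshold,
                 lesion_conc_threshold = lesion_conc_threshold,
                 connectivity = connectivity, n_perm = n_perm,
                 min_patients = min_patients, bh_alpha = bh_alpha,
                 qc_bins = qc_bins, qc_percentile = qc_percentile,
                 sigma_floor = sigma_floor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror [pipeline_config()] arguments; a `sim` block
#' mirrors [sim_config()].
#'
#' @param path YAML (.yaml/.yml, requires the yaml package) or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(lst$sim)) do.call(sim_config, lst$sim)
         else sim_config()
  do.call(pipeline_config, c(list(sim = sim),
                             lst[setdiff(names(lst), "sim")]))
}

#' Run the full pipeline on a synthetic study
#'
#' Stages: simulate the study to disk, fit the normative atlas on the
#' healthy cohort, compute patient z-score maps, build tract masks
#' (merge, normalize, binarize, intersect with brain mask), extract the
#' metric tables, run MI registration QC over the whole MS cohort, and
#' run the correlation/comparison study per cohort.  Every stage's
#' parameters and outputs are logged to a JSON manifest; a plain-text
#' report summarises cohort demographics, QC flags and the top
#' comparisons.  Deterministic given the master seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the run.
#' @return invisibly, a list with the fitted model, metric table, QC
#'   table, study results and the run directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$sim))
    stop("stage 'simulate': no simulation config or dataset given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_log <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_log[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  study <- tick("simulate",
                simulate_study(config$sim, file.path(out_dir, "dataset")))
  gt <- study$ground_truth
  model <- tick("fit_atlas",
                fit_normative_model(study$healthy, gt$brain_mask,
                                    sigma_floor = config$sigma_floor))
  write_normative_model(model, file.path(out_dir, "normative_model"))

  patients <- c(study$early, study$progressive)
  z_maps <- tick("zscore", {
    zs <- lapply(patients, function(p)
      zscore_map(model, p$t1, p$age, p$sex))
    names(zs) <- vapply(patients, `[[`, "", "id")
    zs
  })

  tracts <- tick("tract_masks", {
    defs <- lapply(gt$tracts, function(g)
      tract_definition(g$name, g$abbreviation, g$density, g$class,
                       g$laterality))
    build_tract_masks(defs, config$density_threshold, model$brain_mask)
  })

  metrics <- tick("metrics",
                  build_metric_table(patients, z_maps, tracts,
                                     config$z_threshold,
                                     config$connectivity))
  write_metric_table(metrics, file.path(out_dir, "metrics"))

  qc <- tick("qc", {
    vols <- lapply(patients, `[[`, "t1")
    names(vols) <- names(z_maps)
    qc_cohort(vols, model$beta0, model$brain_mask, config$qc_bins,
              config$qc_percentile)
  })
  utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)

  outcomes <- cohort_summary(patients)[, c("id", "cohort", "edss0",
                                           "delta_edss")]
  names(outcomes)[1L] <- "patient_id"
  study_res <- tick("stats",
                    run_correlation_study(metrics, outcomes,
                                          n_perm = config$n_perm,
                                          min_patients = config$min_patients,
                                          bh_alpha = config$bh_alpha,
                                          master_seed = config$seed))
  utils::write.csv(study_res$correlations,
                   file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(study_res$comparisons,
                   file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE, na = "")

  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), "sim")],
    sim = config$sim[setdiff(names(config$sim),
                             c("age_mean", "age_sd", "female_frac"))],
    stages = stage_log,
    outputs = list(dataset = "dataset", model = "normative_model",
                   metrics = "metrics", qc = "qc.csv",
                   correlations = "correlations.csv",
                   comparisons = "comparisons.csv", report = "report.txt"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_report(file.path(out_dir, "report.txt"), study, qc, study_res)
  invisible(list(model = model, metrics = metrics, qc = qc,
                 study = study_res, dir = out_dir, z_maps = z_maps,
                 tracts = tracts, ground_truth = gt,
                 patients = patients))
}

write_run_report <- function(path, study, qc, res) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("tractnorm pipeline report")
  w("=========================")
  for (co in c("healthy", "early", "progressive")) {
    recs <- switch(co, healthy = study$healthy, early = study$early,
                   progressive = study$progressive)
    if (!length(recs)) next
    cs <- cohort_summary(recs)
    w("%-12s n = %3d, age %.1f +/- %.1f y, %.0f%% female", co, nrow(cs),
      mean(cs$age), stats::sd(cs$age), 100 * mean(cs$sex == 0))
    if (co != "healthy")
      w("             EDSS0 %.2f +/- %.2f, dEDSS %+.2f +/- %.2f",
        mean(cs$edss0), stats::sd(cs$edss0), mean(cs$delta_edss),
        stats::sd(cs$delta_edss))
  }
  w("")
  w("Registration QC: %d / %d flagged (MI threshold %.4f nats)",
    sum(qc$flagged), nrow(qc), qc$threshold[1L])
  w("")
  w("BH-significant permutation comparisons (alpha = %.2f): %d",
    res$config$bh_alpha,
    sum(res$comparisons$p_adj < res$config$bh_alpha, na.rm = TRUE))
  top <- res$comparisons[order(res$comparisons$p_adj), ]
  top <- utils::head(top, 8)
  for (i in seq_len(nrow(top)))
    w("  %-12s %-24s %-5s d = %+.3f  p = %.4f  p_adj = %.4f",
      top$cohort[i], top$family[i], top$tract[i], top$d_obs[i],
      top$p_perm[i], top$p_adj[i])
  invisible(path)
}
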