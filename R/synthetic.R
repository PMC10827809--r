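# Synthetic study generator.
#
# Produces a fully synthetic stand-in for the study: a smooth voxel-wise
# ground-truth normative model, tube-shaped white-matter tracts with
# Gaussian-profile streamline density, a healthy cohort, and two MS-like
# patient cohorts with focal lesions and diffuse NAWM T1 elevation whose
# latent severities drive the EDSS outcomes through monotone links.

#' Simulation configuration
#'
#' Defaults encode the study conditions: cohort sizes 92/47/52, ages
#' 37.3 +/- 10.6 (healthy), 31.8 +/- 8.0 (early), 49.9 +/- 7.2
#' (progressive) years truncated to [18, 75], female fractions
#' 0.63/0.75/0.65, follow-up intervals 24.7 +/- 1.3 and 25.0 +/- 3.7
#' months.  Geometry and lesion burden are scaled to the phantom grid
#' (default 24^3 at 1 mm isotropic) rather than a full head FOV.
#'
#' @param grid integer length-3 grid shape (>= 16 per axis recommended).
#' @param voxel_size voxel edge lengths in mm.
#' @param n_healthy,n_early,n_progressive cohort sizes.
#' @param age_mean,age_sd named numeric: per-cohort age distribution
#'   (truncated normal on `age_range`).
#' @param female_frac named numeric: per-cohort female fraction.
#' @param age_range truncation bounds in years.
#' @param sigma_scale multiplies the ground-truth residual-SD map; 0 gives
#'   the noise-free limit.
#' @param n_tracts number of tract geometries (>= 1); the default set of 4
#'   (CST, CC, ICP, ML) contains two supratentorial and two infratentorial
#'   tracts and one left/right pair.
#' @param lesion_rate named numeric: mean lesion count per patient cohort.
#' @param lesion_radius_range semi-axis range of ellipsoidal lesions, voxels.
#' @param lesion_t1_offset T1 elevation inside lesions (ms).
#' @param off_tract_fraction fraction of lesions placed uniformly in brain
#'   rather than on tract centerlines.
#' @param nawm_effect diffuse NAWM T1 elevation per unit severity at tract
#'   core (ms).
#' @param supra_lesion_weight placement weight multiplying supratentorial
#'   tracts when assigning lesions (MS lesions are predominantly
#'   supratentorial).
#' @param edss0_base,edss0_gain,edss0_noise_sd monotone link from mean
#'   supratentorial severity to baseline EDSS, plus Gaussian noise before
#'   snapping to the half-point grid; `edss0_base` may be named per
#'   patient cohort (progressive patients start far higher on the scale).
#' @param dedss_gain,dedss_noise_sd monotone link from mean infratentorial
#'   severity to 2-year EDSS change.
#' @param severity_shape,severity_rate gamma distribution of the per-tract
#'   latent damage severities (mean shape/rate).
#' @param smooth_noise if TRUE, spatially smooth the voxel noise field
#'   (stress test; default independent voxel noise).
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid = c(24, 24, 24), voxel_size = c(1, 1, 1),
                       n_healthy = 92, n_early = 47, n_progressive = 52,
                       age_mean = c(healthy = 37.3, early = 31.8,
                                    progressive = 49.9),
                       age_sd = c(healthy = 10.6, early = 8.0,
                                  progressive = 7.2),
                       female_frac = c(healthy = 0.63, early = 0.75,
                                       progressive = 0.65),
                       age_range = c(18, 75),
                       sigma_scale = 1,
                       n_tracts = 4,
                       lesion_rate = c(early = 8, progressive = 12),
                       lesion_radius_range = c(1, 2.2),
                       lesion_t1_offset = 300,
                       off_tract_fraction = 0.2,
                       nawm_effect = 60,
                       supra_lesion_weight = 3,
                       edss0_base = c(early = 0.7, progressive = 4.0),
                       edss0_gain = 1.2, edss0_noise_sd = 0.6,
                       dedss_gain = 0.35, dedss_noise_sd = 0.45,
                       severity_shape = 2, severity_rate = 2,
                       smooth_noise = FALSE,
                       seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L),
            all(c("healthy", "early", "progressive") %in% names(age_mean)),
            n_healthy >= 0, n_early >= 0, n_progressive >= 0,
            sigma_scale >= 0, n_tracts >= 0, lesion_t1_offset >= 0,
            off_tract_fraction >= 0, off_tract_fraction <= 1)
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 n_healthy = n_healthy, n_early = n_early,
                 n_progressive = n_progressive,
                 age_mean = age_mean, age_sd = age_sd,
                 female_frac = female_frac, age_range = age_range,
                 sigma_scale = sigma_scale, n_tracts = n_tracts,
                 lesion_rate = lesion_rate,
                 lesion_radius_range = lesion_radius_range,
                 lesion_t1_offset = lesion_t1_offset,
                 off_tract_fraction = off_tract_fraction,
                 nawm_effect = nawm_effect,
                 supra_lesion_weight = supra_lesion_weight,
                 edss0_base = edss0_base, edss0_gain = edss0_gain,
                 edss0_noise_sd = edss0_noise_sd,
                 dedss_gain = dedss_gain, dedss_noise_sd = dedss_noise_sd,
                 severity_shape = severity_shape,
                 severity_rate = severity_rate,
                 smooth_noise = smooth_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# normalized coordinates in [-1, 1] per axis, as three arrays
norm_coords <- function(grid) {
  ax <- lapply(grid, function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n))
  list(u = array(rep(ax[[1L]], times = grid[2L] * grid[3L]), dim = grid),
       v = array(rep(rep(ax[[2L]], each = grid[1L]), times = grid[3L]),
                 dim = grid),
       w = array(rep(ax[[3L]], each = grid[1L] * grid[2L]), dim = grid))
}

# default tract geometry set, in fractional grid coordinates:
# points are (x, y, z) fractions; z < infra_z is "infratentorial" space
default_tract_geometries <- function(n_tracts) {
  base <- list(
    list(abbreviation = "CST", name = "cortico-spinal tract",
         class = "projection", laterality = "left",
         curve = cbind(x = 0.32, y = 0.50, z = seq(0.45, 0.90, length.out = 40)),
         radius = 1.6),
    list(abbreviation = "CST", name = "cortico-spinal tract",
         class = "projection", laterality = "right",
         curve = cbind(x = 0.68, y = 0.50, z = seq(0.45, 0.90, length.out = 40)),
         radius = 1.6),
    list(abbreviation = "CC", name = "corpus callosum",
         class = "commissural", laterality = "midline",
         curve = cbind(x = seq(0.22, 0.78, length.out = 40), y = 0.45,
                       z = 0.72 + 0.10 * sin(seq(0, pi, length.out = 40))),
         radius = 1.6),
    list(abbreviation = "ICP", name = "inferior cerebellar peduncle",
         class = "cerebellar", laterality = "left",
         curve = cbind(x = seq(0.38, 0.30, length.out = 20),
                       y = seq(0.55, 0.68, length.out = 20),
                       z = seq(0.30, 0.16, length.out = 20)),
         radius = 1.4),
    list(abbreviation = "ICP", name = "inferior cerebellar peduncle",
         class = "cerebellar", laterality = "right",
         curve = cbind(x = seq(0.62, 0.70, length.out = 20),
                       y = seq(0.55, 0.68, length.out = 20),
                       z = seq(0.30, 0.16, length.out = 20)),
         radius = 1.4),
    list(abbreviation = "ML", name = "medial lemniscus",
         class = "brainstem", laterality = "midline",
         curve = cbind(x = 0.50, y = 0.42,
                       z = seq(0.08, 0.38, length.out = 30)),
         radius = 1.3))
  # n_tracts counts merged tracts; the default set yields 4 (CST, CC, ICP, ML)
  merged <- unique(vapply(base, `[[`, "", "abbreviation"))
  keep <- merged[seq_len(min(n_tracts, length(merged)))]
  extra <- list()
  if (n_tracts > length(merged)) {
    for (k in seq_len(n_tracts - length(merged))) {
      y0 <- 0.25 + 0.5 * (k %% 3) / 3
      extra[[k]] <- list(abbreviation = paste0("AUX", k),
                         name = paste0("auxiliary bundle ", k),
                         class = "association", laterality = "midline",
                         curve = cbind(x = seq(0.25, 0.75, length.out = 30),
                                       y = y0, z = 0.55 + 0.05 * k / 2),
                         radius = 1.4)
    }
  }
  c(Filter(function(g) g$abbreviation %in% keep, base), extra)
}

#' Is a tract class infratentorial?
#'
#' Brainstem and cerebellar bundles lie below the tentorium; projection,
#' association and commissural tracts are treated as supratentorial.
#'
#' @param tract_class character vector of tract classes.
#' @return logical vector.
#' @export
is_infratentorial <- function(tract_class) {
  tract_class %in% c("brainstem", "cerebellar")
}

# Gaussian-profile tube density around a polyline given in fractional coords
tube_density <- function(grid, voxel_size, geometry) {
  pts <- geometry$curve
  # to voxel index coordinates (1-based), physical distances in voxel units
  # assume near-isotropic voxels for the phantom; distances in mm
  P <- cbind((pts[, 1L] * (grid[1L] - 1) + 1) * voxel_size[1L],
             (pts[, 2L] * (grid[2L] - 1) + 1) * voxel_size[2L],
             (pts[, 3L] * (grid[3L] - 1) + 1) * voxel_size[3L])
  idx <- arrayInd(seq_len(prod(grid)), grid)
  V <- cbind(idx[, 1L] * voxel_size[1L], idx[, 2L] * voxel_size[2L],
             idx[, 3L] * voxel_size[3L])
  d2 <- matrix(Inf, nrow(V), 1L)
  for (i in seq_len(nrow(P))) {
    di <- (V[, 1L] - P[i, 1L])^2 + (V[, 2L] - P[i, 2L])^2 +
      (V[, 3L] - P[i, 3L])^2
    d2 <- pmin(d2, di)
  }
  sigma <- geometry$radius * mean(voxel_size)
  array(exp(-d2 / (2 * sigma^2)), dim = grid)
}

#' Generate the ground-truth normative model and tract set
#'
#' Smooth low-order polynomial coefficient fields over an ellipsoidal
#' brain mask: white-matter-like baseline T1 around 850-950 ms, a small
#' sex offset, a mildly accelerating age slope, and a residual SD around
#' 30 ms.  Tract streamline density decays as a Gaussian of distance from
#' each centerline.
#'
#' @param config a [sim_config()].
#' @return an object of class `ground_truth` with coefficient volumes,
#'   `sigma` map, `brain_mask`, `center_age`, and a list of tract
#'   geometries with density volumes.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  if (config$n_tracts < 1L) stop("config must define at least one tract")
  if (any(grid < 8L))
    stop("grid too small to contain any tube (need >= 8 voxels per axis)")
  vs <- config$voxel_size
  cc <- norm_coords(grid)
  mask_arr <- (cc$u / 0.92)^2 + (cc$v / 0.92)^2 + (cc$w / 0.92)^2 <= 1
  mk <- function(values) {
    a <- array(values, dim = grid)
    a[!mask_arr] <- NaN
    brain_volume(a, vs)
  }
  beta0 <- mk(900 + 25 * cc$u + 15 * cc$v * cc$w - 20 * cc$w^2)
  beta_sex <- mk(8 + 3 * cc$u)
  beta_age <- mk(1.2 + 0.4 * cc$v)
  beta_age2 <- mk(0.02 + 0.01 * cc$w)
  sigma <- mk(config$sigma_scale * (30 + 8 * abs(cc$u)))
  geoms <- default_tract_geometries(config$n_tracts)
  tracts <- lapply(geoms, function(g) {
    g$density <- brain_volume(tube_density(grid, vs, g), vs)
    g
  })
  if (!any(is_infratentorial(vapply(tracts, `[[`, "", "class"))) &&
      config$n_tracts >= 4L)
    stop("internal: default tract set must include an infratentorial tract")
  structure(list(beta0 = beta0, beta_sex = beta_sex, beta_age = beta_age,
                 beta_age2 = beta_age2, sigma = sigma,
                 brain_mask = brain_mask(mask_arr, vs),
                 center_age = unname(config$age_mean["healthy"]),
                 tracts = tracts, config = config),
            class = "ground_truth")
}

# truncated-normal draw by rejection (bounds are ~2 SD out, cheap)
rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# ground-truth expected T1 for one subject (array)
gt_expected_t1 <- function(gt, age, sex) {
  a <- age - gt$center_age
  vol_data(gt$beta0) + sex * vol_data(gt$beta_sex) +
    a * vol_data(gt$beta_age) + a^2 * vol_data(gt$beta_age2)
}

gt_noise <- function(gt) {
  grid <- dim(vol_data(gt$sigma))
  eps <- array(stats::rnorm(prod(grid)), dim = grid)
  if (isTRUE(gt$config$smooth_noise)) eps <- smooth3d(eps)
  s <- vol_data(gt$sigma)
  s[is.na(s)] <- 0
  eps * s
}

# separable 3-tap [1 2 1]/4 smoothing along each axis, edge-replicated;
# rescaled to keep unit marginal variance only approximately (stress test)
smooth3d <- function(a) {
  for (axis in 1:3) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(a, perm)
    n <- dim(b)[1L]
    up <- b[c(1L, seq_len(n - 1L)), , , drop = FALSE]
    dn <- b[c(seq_len(n - 1L) + 1L, n), , , drop = FALSE]
    b <- (up + 2 * b + dn) / 4
    a <- aperm(b, order(perm))
  }
  a / stats::sd(a)
}

#' Simulate a healthy cohort
#'
#' Each subject's T1 at voxel v is the ground-truth normative prediction
#' at (age, sex) plus independent Normal(0, sigma(v)) noise.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @return list of [subject_record()]s with T1 volumes attached.
#' @export
simulate_healthy_cohort <- function(gt, n = gt$config$n_healthy,
                                    seed = gt$config$seed) {
  stopifnot(inherits(gt, "ground_truth"), n >= 1)
  cfg <- gt$config
  set.seed(seed)
  ages <- rtruncnorm_vec(n, cfg$age_mean["healthy"], cfg$age_sd["healthy"],
                         cfg$age_range[1L], cfg$age_range[2L])
  sexes <- stats::rbinom(n, 1L, 1 - cfg$female_frac["healthy"])
  lapply(seq_len(n), function(i) {
    t1 <- gt_expected_t1(gt, ages[i], sexes[i]) + gt_noise(gt)
    subject_record(sprintf("HC%03d", i), ages[i], sexes[i],
                   brain_volume(t1, cfg$voxel_size))
  })
}

# merged tract view of the ground truth: one entry per abbreviation with
# summed density, class, and centerline voxel candidates for lesion seeding
gt_merged_tracts <- function(gt) {
  abbr <- vapply(gt$tracts, `[[`, "", "abbreviation")
  lapply(split(seq_along(abbr), factor(abbr, levels = unique(abbr))),
         function(ix) {
           dens <- Reduce(`+`, lapply(gt$tracts[ix],
                                      function(t) vol_data(t$density)))
           list(abbreviation = gt$tracts[[ix[1L]]]$abbreviation,
                class = gt$tracts[[ix[1L]]]$class, density = dens)
         })
}

snap_edss <- function(x) pmin(10, pmax(0, round(x * 2) / 2))

#' Simulate one MS-like patient
#'
#' Starts from a healthy draw, then: (a) inserts ellipsoidal lesions with
#' T1 elevated by `lesion_t1_offset`, centers sampled on tract voxels with
#' probability proportional to streamline density (a configurable fraction
#' lands off-tract, uniformly in brain); (b) adds diffuse NAWM T1
#' elevation on each tract proportional to that tract's latent severity
#' times the density profile; (c) draws EDSS0 from a monotone link of mean
#' supratentorial severity and the 2-year EDSS change from a monotone link
#' of mean infratentorial severity, both noisy, snapped to the half-point
#' grid and clipped to [0, 10].  Lesion counts per tract scale with the
#' tract's severity, so lesion burden and NAWM damage share the latent
#' cause the downstream correlation analysis looks for.
#'
#' @param gt ground truth.
#' @param cohort `"early"` or `"progressive"`.
#' @param severity optional named non-negative vector of per-tract latent
#'   damage (names = merged tract abbreviations); drawn from the
#'   configured gamma distribution when `NULL`.
#' @param seed integer seed.
#' @param id patient identifier.
#' @return a [patient_record()]; attribute `"severity"` carries the latent
#'   severities used.
#' @export
simulate_patient <- function(gt, cohort = c("early", "progressive"),
                             severity = NULL, seed = NULL, id = "P001") {
  stopifnot(inherits(gt, "ground_truth"))
  cohort <- match.arg(cohort)
  cfg <- gt$config
  if (!is.null(seed)) set.seed(seed)
  grid <- cfg$grid
  mtr <- gt_merged_tracts(gt)
  if (is.null(severity)) {
    severity <- stats::rgamma(length(mtr), shape = cfg$severity_shape,
                              rate = cfg$severity_rate)
    names(severity) <- vapply(mtr, `[[`, "", "abbreviation")
  } else {
    if (is.null(names(severity)))
      names(severity) <- vapply(mtr, `[[`, "", "abbreviation")
    severity <- severity[vapply(mtr, `[[`, "", "abbreviation")]
    if (anyNA(severity) || any(severity < 0))
      stop("severity must be a non-negative vector named by merged tract")
  }
  age <- rtruncnorm_vec(1L, cfg$age_mean[cohort], cfg$age_sd[cohort],
                        cfg$age_range[1L], cfg$age_range[2L])
  sex <- stats::rbinom(1L, 1L, 1 - cfg$female_frac[cohort])
  t1 <- gt_expected_t1(gt, age, sex) + gt_noise(gt)

  infra <- is_infratentorial(vapply(mtr, `[[`, "", "class"))
  # diffuse NAWM elevation: effect * severity * density profile
  for (k in seq_along(mtr))
    t1 <- t1 + cfg$nawm_effect * severity[k] *
      (mtr[[k]]$density / max(mtr[[k]]$density))

  # focal lesions
  lesion <- array(FALSE, dim = grid)
  bm <- vol_data(gt$brain_mask)
  n_les <- stats::rpois(1L, cfg$lesion_rate[cohort])
  if (n_les > 0) {
    if (2 * max(cfg$lesion_radius_range) > min(grid))
      stop("lesion larger than grid")
    w_tract <- severity * ifelse(infra, 1, cfg$supra_lesion_weight)
    brain_idx <- which(bm)
    coords <- arrayInd(seq_len(prod(grid)), grid)
    for (l in seq_len(n_les)) {
      if (stats::runif(1) < cfg$off_tract_fraction || sum(w_tract) == 0) {
        ctr <- coords[brain_idx[sample.int(length(brain_idx), 1L)], ]
      } else {
        k <- sample.int(length(mtr), 1L, prob = w_tract)
        dens <- mtr[[k]]$density
        cand <- which(dens > 0.3 & bm)
        if (!length(cand)) cand <- brain_idx
        ctr <- coords[cand[sample.int(length(cand), 1L,
                                      prob = dens[cand])], ]
      }
      ax <- stats::runif(3L, cfg$lesion_radius_range[1L],
                         cfg$lesion_radius_range[2L])
      d2 <- ((coords[, 1L] - ctr[1L]) / ax[1L])^2 +
        ((coords[, 2L] - ctr[2L]) / ax[2L])^2 +
        ((coords[, 3L] - ctr[3L]) / ax[3L])^2
      lesion[d2 <= 1] <- TRUE
    }
    lesion <- lesion & bm
    t1[lesion] <- t1[lesion] + cfg$lesion_t1_offset
  }

  s_supra <- if (any(!infra)) mean(severity[!infra]) else 0
  s_infra <- if (any(infra)) mean(severity[infra]) else 0
  base0 <- if (length(cfg$edss0_base) > 1L) cfg$edss0_base[[cohort]]
           else cfg$edss0_base[[1L]]
  edss0 <- snap_edss(base0 + cfg$edss0_gain * s_supra +
                       stats::rnorm(1L, 0, cfg$edss0_noise_sd))
  dedss <- snap_edss(cfg$dedss_gain * s_infra +
                       stats::rnorm(1L, 0, cfg$dedss_noise_sd) + 5) - 5
  follow <- snap_edss(edss0 + dedss)
  dt <- if (cohort == "early") stats::rnorm(1L, 24.7, 1.3)
        else stats::rnorm(1L, 25.0, 3.7)
  rec <- patient_record(id, age, sex,
                        t1 = brain_volume(t1, cfg$voxel_size),
                        lesion_mask = brain_mask(lesion, cfg$voxel_size),
                        edss0 = edss0, edss_followup = follow,
                        delta_t_months = dt, cohort = cohort)
  attr(rec, "severity") <- severity
  rec
}

#' Simulate a full patient cohort
#'
#' @inheritParams simulate_patient
#' @param n cohort size.
#' @param seed integer seed (per-patient seeds are drawn from it).
#' @return list of patient records.
#' @export
simulate_patient_cohort <- function(gt, cohort = c("early", "progressive"),
                                    n = NULL, seed = gt$config$seed) {
  cohort <- match.arg(cohort)
  if (is.null(n))
    n <- if (cohort == "early") gt$config$n_early else gt$config$n_progressive
  set.seed(seed)
  pre <- if (cohort == "early") "EMS" else "PMS"
  lapply(seq_len(n), function(i)
    simulate_patient(gt, cohort, seed = NULL,
                     id = sprintf("%s%03d", pre, i)))
}

#' Simulate a study and write it to disk
#'
#' Writes all T1 maps and lesion masks as NIfTI, the brain mask, per-tract
#' density maps plus a TSV manifest, a cohort CSV, and a JSON manifest
#' recording the seed and ground-truth summaries for test oracles.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the ground truth, record lists and paths.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_ground_truth(config)
  healthy <- simulate_healthy_cohort(gt, config$n_healthy, config$seed)
  early <- simulate_patient_cohort(gt, "early", config$n_early,
                                   config$seed + 1L)
  prog <- simulate_patient_cohort(gt, "progressive", config$n_progressive,
                                  config$seed + 2L)
  vdir <- file.path(dir, "volumes"); dir.create(vdir, showWarnings = FALSE)
  tdir <- file.path(dir, "tracts"); dir.create(tdir, showWarnings = FALSE)
  write_volume(gt$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  rows <- list()
  for (r in c(healthy, early, prog)) {
    t1p <- file.path(vdir, paste0(r$id, "_t1.nii.gz"))
    write_volume(r$t1, t1p)
    lp <- NA_character_
    if (inherits(r, "patient_record")) {
      lp <- file.path(vdir, paste0(r$id, "_lesion.nii.gz"))
      write_volume(r$lesion_mask, lp)
    }
    rows[[r$id]] <- data.frame(
      id = r$id, age = r$age, sex = ifelse(r$sex == 1, "M", "F"),
      cohort = if (inherits(r, "patient_record")) r$cohort else "healthy",
      t1_path = t1p, lesion_path = lp,
      edss0 = if (inherits(r, "patient_record")) r$edss0 else NA_real_,
      edss_followup = if (inherits(r, "patient_record"))
        r$edss_followup else NA_real_,
      delta_t_months = if (inherits(r, "patient_record"))
        r$delta_t_months else NA_real_,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE,
                   na = "")
  man_tracts <- do.call(rbind, lapply(seq_along(gt$tracts), function(i) {
    g <- gt$tracts[[i]]
    f <- sprintf("%s_%s_density.nii.gz", g$abbreviation, g$laterality)
    write_volume(g$density, file.path(tdir, f))
    data.frame(file = f, abbreviation = g$abbreviation, name = g$name,
               class = g$class, laterality = g$laterality,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(man_tracts, file.path(tdir, "tracts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = config$seed, grid = config$grid, voxel_size = config$voxel_size,
    n_healthy = config$n_healthy, n_early = config$n_early,
    n_progressive = config$n_progressive,
    center_age = gt$center_age,
    n_brain_voxels = sum(vol_data(gt$brain_mask)),
    tracts = man_tracts$abbreviation,
    mean_beta0 = mean(vol_data(gt$beta0), na.rm = TRUE),
    mean_sigma = mean(vol_data(gt$sigma), na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ground_truth = gt, healthy = healthy, early = early,
                 progressive = prog, dir = dir,
                 cohort_csv = file.path(dir, "cohort.csv"),
                 tract_manifest = file.path(tdir, "tracts.tsv")))
}
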