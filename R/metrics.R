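# Lesion/NAWM compartment metrics.
#
# Conventions (deliberate and test-pinned): mask binarizations use
# inclusive >=; the abnormality count V|z|>2 uses strict > ("larger than
# 2"); empty compartments yield missing values (NA), never zeros, so they
# propagate to pairwise-complete correlation handling downstream.

#' Binarize a lesion concentration map
#'
#' @param conc `brain_volume` with values in [0, 1] (partial-volume lesion
#'   concentration).
#' @param threshold in (0, 1); voxels with concentration >= threshold are
#'   lesional.  Default 0.5.
#' @return a `brain_mask`.
#' @export
binarize_lesion_concentration <- function(conc, threshold = 0.5) {
  stopifnot(inherits(conc, "brain_volume"))
  d <- vol_data(conc)
  fin <- d[is.finite(d)]
  if (any(fin < 0 | fin > 1))
    stop("concentration values must lie in [0, 1]")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  brain_mask(is.finite(d) & d >= threshold, conc$voxel_size, conc$space)
}

#' Split a tract into NAWM and lesion compartments
#'
#' `lesion_on_tract = tract AND lesion`; `nawm = tract AND NOT lesion`.
#' The two are disjoint and their union is the tract mask.
#'
#' @param tract_mask,lesion_mask `brain_mask`s on one grid.
#' @return list with elements `nawm` and `lesion` (`brain_mask`s).
#' @export
split_compartments <- function(tract_mask, lesion_mask) {
  stopifnot(inherits(tract_mask, "brain_mask"),
            inherits(lesion_mask, "brain_mask"))
  stop_unless_same_grid(tract_mask, lesion_mask,
                        what = "tract and lesion masks")
  tm <- vol_data(tract_mask); lm <- vol_data(lesion_mask)
  list(nawm = brain_mask(tm & !lm, tract_mask$voxel_size, tract_mask$space),
       lesion = brain_mask(tm & lm, tract_mask$voxel_size,
                           tract_mask$space))
}

#' Mean absolute z-score over a mask
#'
#' The magnitude of deviation from the norm: mean of |z(v)| over masked
#' voxels with finite z.  `NA` when the compartment has no such voxel.
#'
#' @param z z-score `brain_volume`.
#' @param mask `brain_mask` on the same grid.
#' @return scalar, or `NA_real_` for an empty compartment.
#' @export
mean_abs_z <- function(z, mask) {
  stop_unless_same_grid(z, mask, what = "z map and mask")
  vals <- vol_data(z)[vol_data(mask)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(abs(vals))
}

#' Count abnormal voxels (|z| > threshold) over a mask
#'
#' The spatial extent of deviation from the norm: number of masked voxels
#' whose absolute z-score strictly exceeds the threshold (default 2),
#' also expressed as a volume in mL.
#'
#' @inheritParams mean_abs_z
#' @param z_threshold non-negative absolute z cutoff (strict).
#' @return list with `count` (integer) and `volume_ml`.
#' @export
count_abnormal <- function(z, mask, z_threshold = 2) {
  if (z_threshold < 0) stop("z_threshold must be >= 0")
  stop_unless_same_grid(z, mask, what = "z map and mask")
  vals <- vol_data(z)[vol_data(mask)]
  vals <- vals[is.finite(vals)]
  cnt <- sum(abs(vals) > z_threshold)
  list(count = as.integer(cnt),
       volume_ml = cnt * voxel_volume(mask) / 1000)
}

#' Lesion volume on a tract
#'
#' @param lesion_mask,tract_mask `brain_mask`s on one grid.
#' @return overlap volume in mL (voxel count * voxel volume / 1000).
#' @export
tract_lesion_volume <- function(lesion_mask, tract_mask) {
  stop_unless_same_grid(lesion_mask, tract_mask,
                        what = "lesion and tract masks")
  sum(vol_data(lesion_mask) & vol_data(tract_mask)) *
    voxel_volume(lesion_mask) / 1000
}

# connected-component labelling of a 3D logical array under 6/18/26
# connectivity, via the voxel-adjacency graph
label_components <- function(mask_arr, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  grid <- dim(mask_arr)
  vox <- which(mask_arr)
  if (!length(vox)) return(list(n = 0L, labels = integer(0), voxels = vox))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
             drop = FALSE]
  coords <- arrayInd(vox, grid)
  pos <- match(seq_len(prod(grid)), vox)   # grid index -> voxel rank
  edges <- vector("list", nrow(off))
  for (i in seq_len(nrow(off))) {
    nb <- sweep(coords, 2L, off[i, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= grid[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= grid[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= grid[3L]
    nb_idx <- (nb[ok, 3L] - 1L) * grid[1L] * grid[2L] +
      (nb[ok, 2L] - 1L) * grid[1L] + nb[ok, 1L]
    tgt <- pos[nb_idx]
    src <- which(ok)[!is.na(tgt)]
    tgt <- tgt[!is.na(tgt)]
    if (length(tgt)) edges[[i]] <- cbind(src, tgt)
  }
  E <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(E) && nrow(E))
    g <- igraph::add_edges(g, t(E[E[, 1L] < E[, 2L], , drop = FALSE]))
  comp <- igraph::components(g)
  list(n = comp$no, labels = comp$membership, voxels = vox)
}

#' Total lesion volume and count
#'
#' TLV from the voxel count; TLC as the number of connected components of
#' the lesion mask (26-connectivity by default: faces, edges and corners
#' all connect).
#'
#' @param lesion_mask a `brain_mask`.
#' @param connectivity 6, 18 or 26.
#' @param patient_id optional identifier carried into the result.
#' @return list with `patient_id`, `tlv_ml`, `tlc`.
#' @export
total_lesion_stats <- function(lesion_mask, connectivity = 26,
                               patient_id = NA_character_) {
  stopifnot(inherits(lesion_mask, "brain_mask"))
  lab <- label_components(vol_data(lesion_mask), connectivity)
  list(patient_id = patient_id,
       tlv_ml = length(lab$voxels) * voxel_volume(lesion_mask) / 1000,
       tlc = as.integer(lab$n))
}

#' Build the per-patient, per-tract metric table
#'
#' One row per patient x tract holding LV, mu|z| and V|z|>2 in the NAWM
#' and lesion compartments, plus a global table of TLV/TLC per patient.
#' Empty compartments are flagged as `NA`, never zero-filled.
#'
#' @param patients list of [patient_record()]s with lesion masks.
#' @param z_maps named list (by patient id) of z-score `brain_volume`s.
#' @param tracts named list of `tract_definition`s with masks set (see
#'   [build_tract_masks()]).
#' @param z_threshold absolute z cutoff for the extent metric.
#' @param connectivity connectivity for the lesion count.
#' @return object of class `tract_metric_table`: list with data.frames
#'   `tract_metrics` and `global`.
#' @export
build_metric_table <- function(patients, z_maps, tracts, z_threshold = 2,
                               connectivity = 26) {
  stopifnot(length(patients) >= 1L, length(tracts) >= 1L)
  rows <- list(); glob <- list()
  for (p in patients) {
    z <- z_maps[[p$id]]
    if (is.null(z)) stop("patient without z map: ", p$id)
    stop_unless_same_grid(z, p$lesion_mask, what = "z map and lesion mask")
    glob[[p$id]] <- as.data.frame(
      total_lesion_stats(p$lesion_mask, connectivity, p$id),
      stringsAsFactors = FALSE)
    for (tr in tracts) {
      comp <- split_compartments(tr$mask, p$lesion_mask)
      ab_n <- count_abnormal(z, comp$nawm, z_threshold)
      ab_l <- count_abnormal(z, comp$lesion, z_threshold)
      n_n <- sum(vol_data(comp$nawm)); n_l <- sum(vol_data(comp$lesion))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$id, tract = tr$abbreviation,
        tract_class = tr$tract_class,
        lv_ml = tract_lesion_volume(p$lesion_mask, tr$mask),
        mu_abs_z_nawm = mean_abs_z(z, comp$nawm),
        mu_abs_z_lesion = mean_abs_z(z, comp$lesion),
        v_gt2_nawm = if (n_n) ab_n$count else NA_integer_,
        v_gt2_lesion = if (n_l) ab_l$count else NA_integer_,
        v_gt2_nawm_ml = if (n_n) ab_n$volume_ml else NA_real_,
        v_gt2_lesion_ml = if (n_l) ab_l$volume_ml else NA_real_,
        n_voxels_nawm = n_n, n_voxels_lesion = n_l,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(tract_metrics = do.call(rbind, rows),
                 global = do.call(rbind, glob)),
            class = "tract_metric_table")
}

#' @export
print.tract_metric_table <- function(x, ...) {
  tm <- x$tract_metrics
  cat(sprintf("Tract metric table: %d patients x %d tracts (%d rows)\n",
              length(unique(tm$patient_id)), length(unique(tm$tract)),
              nrow(tm)))
  cat(sprintf("  TLV %.2f +/- %.2f mL, TLC %.1f +/- %.1f\n",
              mean(x$global$tlv_ml), stats::sd(x$global$tlv_ml),
              mean(x$global$tlc), stats::sd(x$global$tlc)))
  invisible(x)
}

#' Write a metric table as long- and wide-format CSVs
#'
#' @param table a `tract_metric_table`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_metric_table <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tm <- table$tract_metrics
  utils::write.csv(tm, file.path(dir, "tract_metrics_wide.csv"),
                   row.names = FALSE, na = "")
  metric_cols <- setdiff(names(tm), c("patient_id", "tract", "tract_class"))
  long <- do.call(rbind, lapply(metric_cols, function(mc)
    data.frame(patient_id = tm$patient_id, tract = tm$tract,
               metric = mc, value = tm[[mc]], stringsAsFactors = FALSE)))
  utils::write.csv(long, file.path(dir, "tract_metrics_long.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(table$global, file.path(dir, "global_lesion_stats.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
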