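mk_mask <- function(idx, grid = c(6, 6, 6), vs = c(1, 1, 1)) {
  m <- array(FALSE, grid); m[idx] <- TRUE
  brain_mask(m, vs)
}
mk_z <- function(vals, grid = c(6, 6, 6)) {
  brain_volume(array(vals, grid))
}

test_that("lesion concentration binarizes with inclusive >=", {
  conc <- brain_volume(array(c(0, 0.4, 0.6, rep(0, 213)), c(6, 6, 6)))
  m <- binarize_lesion_concentration(conc, 0.5)
  expect_identical(as.vector(vol_data(m))[1:3], c(FALSE, FALSE, TRUE))
  half <- brain_volume(array(0.5, c(6, 6, 6)))
  expect_true(all(vol_data(binarize_lesion_concentration(half, 0.5))))
  expect_false(any(vol_data(binarize_lesion_concentration(half, 0.50001))))
  expect_equal(sum(vol_data(binarize_lesion_concentration(
    brain_volume(array(0, c(6, 6, 6))), 0.5))), 0)
  expect_error(binarize_lesion_concentration(mk_z(2), 0.5), "\\[0, 1\\]")
  expect_error(binarize_lesion_concentration(half, 1), "\\(0, 1\\)")
})

test_that("compartment split is a disjoint partition of the tract", {
  set.seed(7)
  tract <- mk_mask(sample(216, 60))
  lesion <- mk_mask(sample(216, 40))
  cp <- split_compartments(tract, lesion)
  n <- vol_data(cp$nawm); l <- vol_data(cp$lesion)
  expect_false(any(n & l))
  expect_identical(n | l, vol_data(tract))
  # degenerate cases
  empty <- mk_mask(integer(0))
  expect_identical(vol_data(split_compartments(tract, empty)$nawm),
                   vol_data(tract))
  expect_equal(sum(vol_data(split_compartments(tract, tract)$nawm)), 0)
})

test_that("mean |z| and abnormal counts follow their stated conventions", {
  z <- mk_z(c(1, -3, 2, rep(0, 213)))
  m3 <- mk_mask(1:3)
  expect_equal(mean_abs_z(z, m3), 2.0)
  expect_equal(mean_abs_z(mk_z(0), m3), 0)
  expect_true(is.na(mean_abs_z(z, mk_mask(integer(0)))))
  # NaN voxels are excluded, not propagated
  zn <- mk_z(c(1, NaN, 3, rep(0, 213)))
  expect_equal(mean_abs_z(zn, m3), 2.0)

  # strict > 2: the 2.0 voxel does not count
  z4 <- mk_z(c(2.0, 2.1, -2.5, 1.9, rep(0, 212)))
  res <- count_abnormal(z4, mk_mask(1:4), 2)
  expect_identical(res$count, 2L)
  expect_equal(res$volume_ml, 2e-3)
  expect_identical(count_abnormal(mk_z(0), m3)$count, 0L)
  expect_error(count_abnormal(z4, m3, -1), ">= 0")
  # monotone non-increasing in the threshold
  set.seed(1)
  zr <- mk_z(rnorm(216)); mall <- mk_mask(1:216)
  cnts <- vapply(c(0, 0.5, 1, 2, 3),
                 function(th) count_abnormal(zr, mall, th)$count, integer(1))
  expect_true(all(diff(cnts) <= 0))
})

test_that("null calibration: half-normal mean and tail fraction", {
  set.seed(42)
  grid <- c(100, 100, 100)
  z <- brain_volume(array(rnorm(1e6), grid))
  mask <- brain_mask(array(TRUE, grid))
  expect_lt(abs(mean_abs_z(z, mask) - sqrt(2 / pi)), 0.003)
  frac <- count_abnormal(z, mask, 2)$count / 1e6
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.001)
})

test_that("tract lesion volume respects voxel geometry", {
  les <- mk_mask(1:10)
  expect_equal(tract_lesion_volume(les, mk_mask(1:216)), 0.01)
  expect_equal(tract_lesion_volume(les, mk_mask(100:120)), 0)
  les12 <- mk_mask(1:100, vs = c(1, 1, 1.2))
  tr12 <- mk_mask(1:216, vs = c(1, 1, 1.2))
  expect_equal(tract_lesion_volume(les12, tr12), 0.12)
  expect_error(tract_lesion_volume(les, tr12), "grid")
})

test_that("TLV/TLC match a flood-fill oracle incl. corner-touching blobs", {
  expect_equal(total_lesion_stats(mk_mask(integer(0)))$tlv_ml, 0)
  expect_identical(total_lesion_stats(mk_mask(integer(0)))$tlc, 0L)

  grid <- c(10, 10, 10)
  m <- array(FALSE, grid)
  m[1:2, 1:2, 1:2] <- TRUE          # blob of 8
  m[7:8, 7:8, 7] <- TRUE            # blob of 4, far away
  st <- total_lesion_stats(brain_mask(m))
  expect_equal(st$tlv_ml, 12 / 1000)
  expect_identical(st$tlc, 2L)

  # corner contact: one component under 26-connectivity, two under 6
  m2 <- array(FALSE, grid)
  m2[1:2, 1:2, 1:2] <- TRUE
  m2[3, 3, 3] <- TRUE
  expect_identical(total_lesion_stats(brain_mask(m2), 26)$tlc, 1L)
  expect_identical(total_lesion_stats(brain_mask(m2), 6)$tlc, 2L)

  set.seed(5)
  for (i in 1:10) {
    mr <- array(runif(5^3) < 0.2, c(5, 5, 5))
    for (conn in c(6, 26)) {
      expect_identical(total_lesion_stats(brain_mask(mr), conn)$tlc,
                       oracle_components(mr, conn))
    }
  }
})

test_that("metric table: one row per patient x tract, NA for empty compartments", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 3)
  m <- fit_normative_model(hc, gt$brain_mask)
  defs <- lapply(gt$tracts, function(g)
    tract_definition(g$name, g$abbreviation, g$density, g$class,
                     g$laterality))
  masks <- build_tract_masks(defs, 0.05, gt$brain_mask)
  pats <- simulate_patient_cohort(gt, "early", 2, seed = 77)
  zs <- lapply(pats, function(p) zscore_map(m, p$t1, p$age, p$sex))
  names(zs) <- vapply(pats, `[[`, "", "id")
  tab <- build_metric_table(pats, zs, masks)
  expect_equal(nrow(tab$tract_metrics), 2 * length(masks))
  expect_equal(nrow(tab$global), 2)

  # lesion-free patient: lesion-compartment metrics NA, NAWM present
  sev0 <- setNames(numeric(4), names(masks))
  cfg0 <- tiny_config(); cfg0$lesion_rate[] <- 0
  gt0 <- generate_ground_truth(cfg0)
  p0 <- simulate_patient(gt0, "early", severity = sev0, seed = 5)
  z0 <- zscore_map(m, p0$t1, p0$age, p0$sex)
  tab0 <- build_metric_table(list(p0), setNames(list(z0), p0$id), masks)
  expect_true(all(is.na(tab0$tract_metrics$mu_abs_z_lesion)))
  expect_true(all(is.finite(tab0$tract_metrics$mu_abs_z_nawm)))
  expect_true(all(tab0$tract_metrics$lv_ml == 0))
  expect_identical(tab0$global$tlc, 0L)

  # a lesion entirely inside tract A: LV(A) = TLV, LV(disjoint B) = 0
  grid <- dim(vol_data(gt$brain_mask))
  lesion <- array(FALSE, grid); lesion[10:12, 8, 8] <- TRUE
  pl <- pats[[1]]; pl$lesion_mask <- brain_mask(lesion, pl$t1$voxel_size)
  tA <- masks[["ML"]]; inA <- vol_data(tA$mask)
  stopifnot(any(inA))  # fixture sanity
  lesA <- array(FALSE, grid); lesA[which(inA)[1:3]] <- TRUE
  pl$lesion_mask <- brain_mask(lesA, pl$t1$voxel_size)
  tabA <- build_metric_table(list(pl), zs[pl$id], masks)
  tm <- tabA$tract_metrics
  expect_equal(tm$lv_ml[tm$tract == "ML"], tabA$global$tlv_ml)
  expect_equal(tm$lv_ml[tm$tract == "CC"], 0)
  expect_error(build_metric_table(pats, zs["nope"], masks), "without z map")
})

test_that("compartment means recombine to the whole-tract mean", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 3)
  m <- fit_normative_model(hc, gt$brain_mask)
  p <- simulate_patient_cohort(gt, "early", 1, seed = 12)[[1]]
  z <- zscore_map(m, p$t1, p$age, p$sex)
  defs <- lapply(gt$tracts, function(g)
    tract_definition(g$name, g$abbreviation, g$density, g$class,
                     g$laterality))
  masks <- build_tract_masks(defs, 0.05, gt$brain_mask)
  for (t in masks) {
    cp <- split_compartments(t$mask, p$lesion_mask)
    n_n <- sum(vol_data(cp$nawm)); n_l <- sum(vol_data(cp$lesion))
    expect_equal(n_n + n_l, sum(vol_data(t$mask)))
    mu_whole <- mean_abs_z(z, t$mask)
    mu_n <- mean_abs_z(z, cp$nawm); mu_l <- mean_abs_z(z, cp$lesion)
    parts <- c(if (n_n) mu_n * n_n, if (n_l) mu_l * n_l)
    expect_equal(mu_whole, sum(parts) / (n_n + n_l), tolerance = 1e-10)
  }
  # sum of LV over disjoint tracts <= TLV
  lv <- vapply(masks, function(t)
    tract_lesion_volume(p$lesion_mask, t$mask), numeric(1))
  tlv <- total_lesion_stats(p$lesion_mask)$tlv_ml
  overlap_free <- Reduce(`+`, lapply(masks, function(t)
    vol_data(t$mask) * 1))
  if (max(overlap_free) <= 1) expect_lte(sum(lv), tlv + 1e-12)
})
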