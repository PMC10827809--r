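test_that("constant cohort recovers a constant intercept and floors sigma", {
  cohort <- constant_cohort(8, value = 900)
  suppressMessages(m <- fit_normative_model(cohort, full_mask()))
  expect_equal(unique(as.vector(vol_data(m$beta0))), 900)
  expect_equal(max(abs(vol_data(m$beta_sex))), 0, tolerance = 1e-10)
  expect_equal(max(abs(vol_data(m$beta_age))), 0, tolerance = 1e-10)
  expect_equal(unique(as.vector(vol_data(m$sigma))), m$sigma_floor)
  expect_gt(m$n_sigma_floored, 0)
})

test_that("degenerate cohorts are refused with a named cause", {
  expect_error(fit_normative_model(constant_cohort(4), full_mask()),
               "insufficient degrees of freedom")
  same_sex <- constant_cohort(8)
  for (i in seq_along(same_sex)) same_sex[[i]]$sex <- 0L
  expect_error(fit_normative_model(same_sex, full_mask()), "sex")
  same_age <- constant_cohort(8)
  for (i in seq_along(same_age)) same_age[[i]]$age <- 40
  expect_error(fit_normative_model(same_age, full_mask()), "age")
})

test_that("per-voxel coefficients match an independent least-squares oracle", {
  gt <- tiny_gt(grid = c(8, 8, 8))
  hc <- simulate_healthy_cohort(gt, 10, seed = 4)
  m <- fit_normative_model(hc, gt$brain_mask)
  ages <- vapply(hc, `[[`, numeric(1), "age")
  sexes <- vapply(hc, `[[`, numeric(1), "sex")
  a <- ages - m$center_age
  X <- cbind(1, sexes, a, a^2)
  midx <- which(vol_data(gt$brain_mask))
  set.seed(1)
  for (v in sample(midx, 40)) {
    y <- vapply(hc, function(s) s$t1$data[v], numeric(1))
    beta <- oracle_ls(X, y)
    expect_lt(abs(vol_data(m$beta0)[v] - beta[1]), 1e-8)
    expect_lt(abs(vol_data(m$beta_sex)[v] - beta[2]), 1e-8)
    expect_lt(abs(vol_data(m$beta_age)[v] - beta[3]), 1e-8)
    expect_lt(abs(vol_data(m$beta_age2)[v] - beta[4]), 1e-8)
    # unbiased residual SD with denominator n - 4
    res <- y - X %*% beta
    expect_equal(vol_data(m$sigma)[v],
                 max(sqrt(sum(res^2) / (length(y) - 4)), m$sigma_floor),
                 tolerance = 1e-8)
  }
})

test_that("prediction obeys the centering identities", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 8)
  m <- fit_normative_model(hc, gt$brain_mask)
  p00 <- predict(m, m$center_age, 0)
  expect_equal(vol_data(p00), vol_data(m$beta0))
  p10 <- predict(m, m$center_age, 1)
  expect_equal(vol_data(p10), vol_data(m$beta0) + vol_data(m$beta_sex))
  p_age <- predict(m, m$center_age + 10, 1)
  expect_equal(vol_data(p_age),
               vol_data(m$beta0) + vol_data(m$beta_sex) +
                 10 * vol_data(m$beta_age) + 100 * vol_data(m$beta_age2))
  # NaN outside the brain mask
  expect_true(all(is.nan(vol_data(p00)[!vol_data(gt$brain_mask)])))
})

test_that("z-score identities: zero at prediction, one at prediction + sigma", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 8)
  m <- fit_normative_model(hc, gt$brain_mask)
  bm <- vol_data(gt$brain_mask)
  pred <- predict(m, 44, 1)
  z0 <- zscore_map(m, pred, 44, 1)
  expect_equal(max(abs(vol_data(z0)[bm])), 0, tolerance = 1e-12)
  plus <- brain_volume(vol_data(pred) + vol_data(m$sigma),
                       pred$voxel_size, pred$space)
  z1 <- zscore_map(m, plus, 44, 1)
  expect_equal(range(vol_data(z1)[bm]), c(1, 1), tolerance = 1e-12)
  # grid mismatch refused
  small <- brain_volume(array(900, dim = c(8, 8, 8)))
  expect_error(zscore_map(m, small, 44, 1), "grid")
})

test_that("in-sample residuals average to zero and shifts move only beta0", {
  gt <- tiny_gt(grid = c(8, 8, 8))
  hc <- simulate_healthy_cohort(gt, 10, seed = 6)
  m <- fit_normative_model(hc, gt$brain_mask)
  bm <- vol_data(gt$brain_mask)
  resid_sum <- array(0, dim = dim(bm))
  for (s in hc)
    resid_sum <- resid_sum + vol_data(s$t1) -
      vol_data(predict(m, s$age, s$sex))
  expect_lt(max(abs(resid_sum[bm] / length(hc))),
            1e-6 * min(vol_data(m$sigma)[bm]))
  # equivariance: adding c to all training T1 shifts beta0 by c only
  shifted <- lapply(hc, function(s) {
    s$t1 <- brain_volume(vol_data(s$t1) + 50, s$t1$voxel_size, s$t1$space)
    s
  })
  m2 <- fit_normative_model(shifted, gt$brain_mask)
  expect_equal(vol_data(m2$beta0)[bm], vol_data(m$beta0)[bm] + 50,
               tolerance = 1e-8)
  expect_equal(vol_data(m2$sigma)[bm], vol_data(m$sigma)[bm],
               tolerance = 1e-8)
  patient <- hc[[1]]
  shifted_patient <- brain_volume(vol_data(patient$t1) + 50,
                                  patient$t1$voxel_size, patient$t1$space)
  z_a <- zscore_map(m, patient$t1, patient$age, patient$sex)
  z_b <- zscore_map(m2, shifted_patient, patient$age, patient$sex)
  expect_equal(vol_data(z_a)[bm], vol_data(z_b)[bm], tolerance = 1e-8)
})

test_that("model persists to NIfTI + JSON and loads back", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 8)
  m <- fit_normative_model(hc, gt$brain_mask)
  dir <- withr::local_tempdir()
  write_normative_model(m, dir)
  m2 <- read_normative_model(dir)
  for (f in c("beta0", "beta_sex", "beta_age", "beta_age2", "sigma"))
    expect_equal(vol_data(m2[[f]]), vol_data(m[[f]]), tolerance = 0)
  expect_equal(m2$center_age, m$center_age)
  expect_equal(m2$n_train, m$n_train)
  z1 <- zscore_map(m, hc[[1]]$t1, hc[[1]]$age, hc[[1]]$sex)
  z2 <- zscore_map(m2, hc[[1]]$t1, hc[[1]]$age, hc[[1]]$sex)
  expect_equal(vol_data(z1), vol_data(z2))
})

test_that("model methods print, summarise and simulate", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 8)
  m <- fit_normative_model(hc, gt$brain_mask)
  expect_output(print(m), "normative T1 model")
  expect_output(print(summary(m)), "quantiles")
  expect_named(coef(m), c("beta0", "beta_sex", "beta_age", "beta_age2"))
  sims <- simulate(m, nsim = 2, seed = 1, age = 40, sex = 0)
  expect_length(sims, 2)
  bm <- vol_data(gt$brain_mask)
  z <- zscore_map(m, sims[[1]], 40, 0)
  expect_lt(abs(mean(vol_data(z)[bm])), 0.15)
})
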