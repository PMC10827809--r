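test_that("Spearman matches the rank-then-Pearson oracle including ties", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1.0)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(10, 20, 30, 40)),
               oracle_spearman(c(1, 2, 2, 4), c(10, 20, 30, 40)),
               tolerance = 1e-12)
  set.seed(20)
  for (i in 1:50) {
    x <- sample(1:6, 15, replace = TRUE)   # heavy ties
    y <- rnorm(15) + x / 3
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  x <- rnorm(30); y <- rnorm(30) + 0.5 * x
  expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
  expect_equal(spearman_rho(x, rank(y)), spearman_rho(x, y))
  # pairwise-complete deletion
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(spearman_rho(xm, ym), spearman_rho(x, y))
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
  expect_message(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("metric comparison: identical metrics give d = 0, p near 1", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  res <- permutation_compare_metrics(x, x, y, n_perm = 500, sided = "two",
                                     seed = 1)
  expect_equal(res$d_obs, 0)
  expect_gt(res$p, 0.99)
  # add-one bounds
  res2 <- permutation_compare_metrics(x, rnorm(30), y, n_perm = 500,
                                      seed = 2)
  expect_gte(res2$p, 1 / 501)
  expect_lte(res2$p, 1)
  # determinism under a fixed seed
  xB <- rnorm(30)
  r1 <- permutation_compare_metrics(x, xB, y, n_perm = 300, seed = 7)
  r2 <- permutation_compare_metrics(x, xB, y, n_perm = 300, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_error(permutation_compare_metrics(x, xB, y[-1]), "aligned")
  expect_warning(permutation_compare_metrics(x, xB, y, n_perm = 50,
                                             seed = 1), "coarse")
})

test_that("outcome comparison shares one permutation across both outcomes", {
  set.seed(6)
  x <- rnorm(40); yA <- rnorm(40)
  res <- permutation_compare_outcomes(x, yA, yA, n_perm = 400, seed = 3)
  expect_equal(res$d_obs, 0)
  expect_gt(res$p, 0.99)
  yB <- rnorm(40)
  r1 <- permutation_compare_outcomes(x, yA, yB, n_perm = 400, seed = 9)
  r2 <- permutation_compare_outcomes(x, yA, yB, n_perm = 400, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_s3_class(r1, "perm_comparison")
  expect_output(print(r1), "Permutation comparison")
})

test_that("d_obs is antisymmetric and swapped one-sided p's nearly sum to 1", {
  set.seed(12)
  for (i in 1:5) {
    y <- rnorm(25)
    xA <- y + rnorm(25); xB <- rnorm(25)
    ra <- permutation_compare_metrics(xA, xB, y, n_perm = 400,
                                      sided = "one", seed = 100 + i)
    rb <- permutation_compare_metrics(xB, xA, y, n_perm = 400,
                                      sided = "one", seed = 100 + i)
    expect_equal(ra$d_obs, -rb$d_obs, tolerance = 1e-12)
    expect_lte(ra$p + rb$p, 1 + 2 / 401 + 1e-12)
  }
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(30)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(1.2), "\\(0, 1\\]")
  # NAs pass through without disturbing the rest
  expect_equal(bh_adjust(c(0.02, NA, 0.04)),
               c(oracle_bh(c(0.02, 0.04))[1], NA,
                 oracle_bh(c(0.02, 0.04))[2]))
})

test_that("Wilcoxon rank-sum matches exact enumeration and wilcox.test", {
  r <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 6)
  expect_equal(r$p.value, 0.1)
  same <- wilcoxon_ranksum(c(5, 6, 7), c(5, 6, 7))
  expect_gte(same$p.value, 0.99)
  set.seed(40)
  for (i in 1:30) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- sample(1:8, n1, replace = TRUE)   # ties common
    b <- sample(1:8, n2, replace = TRUE)
    res <- wilcoxon_ranksum(a, b)
    # brute-force rank-sum statistic
    expect_equal(res$statistic, sum(rank(c(a, b))[seq_len(n1)]))
    expect_gte(res$p.value, 0)
    expect_lte(res$p.value, 1)
  }
  # large tie-free samples agree with wilcox.test's normal approximation
  set.seed(41)
  a <- rnorm(20); b <- rnorm(25) + 0.5
  res <- wilcoxon_ranksum(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  # convert: wilcox.test W = ranksum - n1(n1+1)/2
  expect_equal(res$statistic - 20 * 21 / 2, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("lesion support filter keeps only sufficiently lesioned tracts", {
  tm <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:6), each = 3),
    tract = rep(c("A", "B", "C"), 6),
    lv_ml = c(rbind(c(1, 1, 1, 1, 1, 0),    # A: 5 patients
                    c(1, 0, 0, 0, 0, 0),    # B: 1 patient
                    rep(0, 6))))            # C: 0 patients
  expect_setequal(lesion_support_filter(tm, 5), "A")
  expect_setequal(lesion_support_filter(tm, 1), c("A", "B"))
  expect_false("C" %in% lesion_support_filter(tm, 1))
})

test_that("run_correlation_study produces all families with BH per family", {
  gt <- tiny_gt()
  hc <- simulate_healthy_cohort(gt, 12, seed = 3)
  m <- fit_normative_model(hc, gt$brain_mask)
  defs <- lapply(gt$tracts, function(g)
    tract_definition(g$name, g$abbreviation, g$density, g$class,
                     g$laterality))
  masks <- build_tract_masks(defs, 0.05, gt$brain_mask)
  pats <- simulate_patient_cohort(gt, "early", 12, seed = 55)
  zs <- lapply(pats, function(p) zscore_map(m, p$t1, p$age, p$sex))
  names(zs) <- vapply(pats, `[[`, "", "id")
  tab <- build_metric_table(pats, zs, masks)
  outc <- cohort_summary(pats)[, c("id", "cohort", "edss0", "delta_edss")]
  names(outc)[1] <- "patient_id"
  st <- run_correlation_study(tab, outc, n_perm = 200, min_patients = 1,
                              master_seed = 5)
  expect_s3_class(st, "correlation_study")
  # 4 tracts x 5 metrics x 2 outcomes + 2 global x 2 outcomes
  expect_equal(nrow(st$correlations), 4 * 5 * 2 + 4)
  expect_setequal(unique(st$comparisons$family),
                  c("mu_vs_v_nawm", "mu_vs_v_lesion", "mu_nawm_vs_lv",
                    "mu_lesion_vs_lv", "edss0_vs_dedss_mu_nawm",
                    "edss0_vs_dedss_mu_lesion", "edss0_vs_dedss_lv"))
  # BH is applied within (cohort, family): p_adj >= p_perm, same ordering
  for (f in unique(st$comparisons$family)) {
    sub <- st$comparisons[st$comparisons$family == f, ]
    expect_equal(sub$p_adj, oracle_bh(sub$p_perm), tolerance = 1e-12)
  }
  # reruns with the same master seed reproduce identically
  st2 <- run_correlation_study(tab, outc, n_perm = 200, min_patients = 1,
                               master_seed = 5)
  expect_identical(st$comparisons$p_perm, st2$comparisons$p_perm)
  # small cohorts are refused
  outc_small <- outc[1:5, ]
  tab_small <- tab
  tab_small$tract_metrics <-
    tab$tract_metrics[tab$tract_metrics$patient_id %in%
                        outc_small$patient_id, ]
  expect_error(run_correlation_study(tab_small, outc_small, n_perm = 100),
               "n = 5 < 10")
})
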