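# Correlation of tract metrics with disability, permutation comparison
# of dependent Spearman correlations, and multiplicity correction.
#
# Permutation p-values use the add-one estimator (1 + #extreme) /
# (n_perm + 1), so p is never 0 and never exceeds 1.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked x and y, with pairwise-complete
#' deletion of missing entries.
#'
#' @param x,y numeric vectors of equal length with >= 3 pairwise-complete
#'   pairs.
#' @return rho in [-1, 1]; `NA_real_` (with a message) when either vector
#'   is constant after deletion.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 pairwise-complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    message("spearman_rho: constant vector, correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

# centered unit-norm rank vector; rho = crossprod of two such vectors
norm_ranks <- function(x) {
  r <- rank(x)
  r <- r - mean(r)
  n <- sqrt(sum(r^2))
  if (n == 0) return(NULL)
  r / n
}

perm_matrix <- function(n, n_perm) {
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

perm_pvalue <- function(d_obs, d_star, sided) {
  n_perm <- length(d_star)
  if (sided == "one") (1 + sum(d_star >= d_obs)) / (n_perm + 1)
  else (1 + sum(abs(d_star) >= abs(d_obs))) / (n_perm + 1)
}

new_perm_comparison <- function(rho_A, rho_B, d_obs, p, sided, n_perm,
                                n_used, seed) {
  structure(list(rho_A = rho_A, rho_B = rho_B, d_obs = d_obs, p = p,
                 sided = sided, n_perm = n_perm, n_used = n_used,
                 seed = seed),
            class = "perm_comparison")
}

#' @export
print.perm_comparison <- function(x, ...) {
  cat(sprintf(paste0("Permutation comparison of |Spearman rho|\n",
                     "  |rho_A| = %.3f, |rho_B| = %.3f, d_obs = %+.3f\n",
                     "  %s-sided p = %.4g  (n = %d, %d permutations)\n"),
              abs(x$rho_A), abs(x$rho_B), x$d_obs, x$sided, x$p,
              x$n_used, x$n_perm))
  invisible(x)
}

#' Compare two metrics' correlations with one outcome
#'
#' Tests d = |rho(xA, y)| - |rho(xB, y)| by randomizing the order of the
#' outcome y across patients: each permutation recomputes both
#' correlations against the same permuted y (the xA-xB dependence is
#' preserved).  One-sided tests reject for large positive d.
#'
#' @param xA,xB metric vectors aligned on the same patients.
#' @param y outcome vector (EDSS), same alignment.
#' @param n_perm number of permutations (default 5000; < 100 warns).
#' @param sided `"one"` or `"two"`.
#' @param seed optional seed.
#' @return a `perm_comparison` object.
#' @export
permutation_compare_metrics <- function(xA, xB, y, n_perm = 5000,
                                        sided = c("one", "two"),
                                        seed = NULL) {
  sided <- match.arg(sided)
  if (length(xA) != length(y) || length(xB) != length(y))
    stop("xA, xB and y must be aligned (equal lengths)")
  if (n_perm < 100) warning("n_perm < 100: permutation p is very coarse")
  if (!is.null(seed)) set.seed(seed)
  ok <- is.finite(xA) & is.finite(xB) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 complete triples")
  a <- norm_ranks(xA[ok]); b <- norm_ranks(xB[ok]); ry <- norm_ranks(y[ok])
  if (is.null(a) || is.null(b) || is.null(ry))
    stop("constant vector: Spearman correlation undefined")
  rho_A <- sum(a * ry); rho_B <- sum(b * ry)
  d_obs <- abs(rho_A) - abs(rho_B)
  P <- matrix(ry[perm_matrix(sum(ok), n_perm)], nrow = sum(ok))
  d_star <- abs(drop(crossprod(a, P))) - abs(drop(crossprod(b, P)))
  new_perm_comparison(rho_A, rho_B, d_obs,
                      perm_pvalue(d_obs, d_star, sided), sided, n_perm,
                      sum(ok), seed)
}

#' Compare one metric's correlations with two outcomes
#'
#' Tests d = |rho(x, yA)| - |rho(x, yB)| (e.g. EDSS0 vs its 2-year
#' change).  Each permutation reorders both outcome vectors with one
#' shared permutation, preserving the yA-yB dependence while breaking the
#' metric-outcome link.
#'
#' @param x metric vector.
#' @param yA,yB outcome vectors aligned with x.
#' @inheritParams permutation_compare_metrics
#' @return a `perm_comparison` object.
#' @export
permutation_compare_outcomes <- function(x, yA, yB, n_perm = 5000,
                                         sided = c("two", "one"),
                                         seed = NULL) {
  sided <- match.arg(sided)
  if (length(yA) != length(x) || length(yB) != length(x))
    stop("x, yA and yB must be aligned (equal lengths)")
  if (n_perm < 100) warning("n_perm < 100: permutation p is very coarse")
  if (!is.null(seed)) set.seed(seed)
  ok <- is.finite(x) & is.finite(yA) & is.finite(yB)
  if (sum(ok) < 3L) stop("need >= 3 complete triples")
  rx <- norm_ranks(x[ok]); ra <- norm_ranks(yA[ok]); rb <- norm_ranks(yB[ok])
  if (is.null(rx) || is.null(ra) || is.null(rb))
    stop("constant vector: Spearman correlation undefined")
  rho_A <- sum(rx * ra); rho_B <- sum(rx * rb)
  d_obs <- abs(rho_A) - abs(rho_B)
  Pm <- perm_matrix(sum(ok), n_perm)
  PA <- matrix(ra[Pm], nrow = sum(ok)); PB <- matrix(rb[Pm], nrow = sum(ok))
  d_star <- abs(drop(crossprod(rx, PA))) - abs(drop(crossprod(rx, PB)))
  new_perm_comparison(rho_A, rho_B, d_obs,
                      perm_pvalue(d_obs, d_star, sided), sided, n_perm,
                      sum(ok), seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across a family of tests (here: across white
#' matter tracts within one hypothesis family).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  keep <- !is.na(p)
  if (any(p[keep] <= 0 | p[keep] > 1))
    stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[keep] <- stats::p.adjust(p[keep], method = "BH")
  out
}

#' Retain tracts with enough lesioned patients
#'
#' Lesion-compartment analyses drop tracts lesioned in fewer than
#' `min_patients` patients (mirroring the exclusion of sparsely lesioned
#' tracts from lesion-related statistics).
#'
#' @param table a `tract_metric_table` (or its `tract_metrics` data.frame
#'   with columns `tract` and `lv_ml`).
#' @param min_patients minimum number of patients with LV > 0.
#' @return character vector of retained tract abbreviations.
#' @export
lesion_support_filter <- function(table, min_patients = 5) {
  tm <- if (inherits(table, "tract_metric_table")) table$tract_metrics
        else table
  counts <- tapply(tm$lv_ml > 0, tm$tract, sum)
  names(counts)[!is.na(counts) & counts >= min_patients]
}

#' Wilcoxon rank-sum test
#'
#' Statistic: sum of (average, tie-sharing) ranks of the first sample in
#' the pooled ordering.  Exact two-sided p by enumeration of all
#' assignments when the combined sample size is <= 12 (ties included);
#' otherwise a tie-corrected normal approximation.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `statistic` (rank sum of `a`), `p.value`, `method`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  if (N <= 12L) {
    combs <- utils::combn(N, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    mu <- n1 * (N + 1) / 2
    p <- min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    mu <- n1 * (N + 1) / 2
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tiecor)
    z <- (w - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p.value = p, method = method)
}

# deterministic per-test seeds derived from one master seed
derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full correlation and comparison study
#'
#' For each cohort and tract, Spearman correlations of the tract metrics
#' (LV, mu|z| and V|z|>2 in NAWM and lesions) and the global lesion
#' metrics (TLV, TLC) with both outcomes (EDSS0 and its 2-year change),
#' with asymptotic t-approximation p-values.  Seven comparison families
#' are tested by permutation and BH-adjusted across tracts within each
#' family:
#' magnitude-vs-extent (mu|z| vs V|z|>2; NAWM and lesions; two-sided),
#' z-metric-vs-lesion-load (mu|z| NAWM / lesions vs LV; one-sided,
#' alternative: z metric correlates more strongly), and
#' current-vs-future disability (EDSS0 vs delta-EDSS for mu|z| NAWM,
#' mu|z| lesions, and LV; two-sided).
#' Lesion-compartment families are restricted to tracts passing
#' [lesion_support_filter()].
#'
#' @param table a `tract_metric_table` from [build_metric_table()].
#' @param outcomes data.frame with columns `patient_id`, `cohort`,
#'   `edss0`, `delta_edss`.
#' @param n_perm permutations per comparison.
#' @param min_patients lesion-support cutoff.
#' @param bh_alpha significance level applied to adjusted p-values in the
#'   printed summary.
#' @param master_seed seed from which per-test permutation seeds derive.
#' @return object of class `correlation_study`: list of data.frames
#'   `correlations` and `comparisons` plus the configuration.
#' @export
run_correlation_study <- function(table, outcomes, n_perm = 5000,
                                  min_patients = 5, bh_alpha = 0.05,
                                  master_seed = 1L) {
  stopifnot(inherits(table, "tract_metric_table"),
            all(c("patient_id", "cohort", "edss0", "delta_edss") %in%
                  names(outcomes)))
  tm <- merge(table$tract_metrics, outcomes, by = "patient_id")
  gl <- merge(table$global, outcomes, by = "patient_id")
  cors <- list(); comps <- list()
  families <- list(
    list(id = "mu_vs_v_nawm", metric_A = "mu_abs_z_nawm",
         metric_B = "v_gt2_nawm", outcome = "edss0", sided = "two",
         type = "metrics", lesion = FALSE),
    list(id = "mu_vs_v_lesion", metric_A = "mu_abs_z_lesion",
         metric_B = "v_gt2_lesion", outcome = "edss0", sided = "two",
         type = "metrics", lesion = TRUE),
    list(id = "mu_nawm_vs_lv", metric_A = "mu_abs_z_nawm",
         metric_B = "lv_ml", outcome = "edss0", sided = "one",
         type = "metrics", lesion = FALSE),
    list(id = "mu_lesion_vs_lv", metric_A = "mu_abs_z_lesion",
         metric_B = "lv_ml", outcome = "edss0", sided = "one",
         type = "metrics", lesion = TRUE),
    list(id = "edss0_vs_dedss_mu_nawm", metric_A = "mu_abs_z_nawm",
         sided = "two", type = "outcomes", lesion = FALSE),
    list(id = "edss0_vs_dedss_mu_lesion", metric_A = "mu_abs_z_lesion",
         sided = "two", type = "outcomes", lesion = TRUE),
    list(id = "edss0_vs_dedss_lv", metric_A = "lv_ml",
         sided = "two", type = "outcomes", lesion = FALSE))
  metric_cols <- c("lv_ml", "mu_abs_z_nawm", "mu_abs_z_lesion",
                   "v_gt2_nawm", "v_gt2_lesion")
  for (co in unique(outcomes$cohort)) {
    sub <- tm[tm$cohort == co, ]
    gsub <- gl[gl$cohort == co, ]
    n_pat <- length(unique(sub$patient_id))
    if (n_pat < 10L)
      stop("cohort '", co, "' has n = ", n_pat, " < 10: refusing")
    tracts <- unique(sub$tract)
    retained <- lesion_support_filter(sub, min_patients)
    # correlations: per tract per metric per outcome
    for (tr in tracts) {
      st <- sub[sub$tract == tr, ]
      for (mc in metric_cols) for (oc in c("edss0", "delta_edss")) {
        ok <- is.finite(st[[mc]]) & is.finite(st[[oc]])
        rho <- if (sum(ok) >= 3L && stats::var(st[[mc]][ok]) > 0 &&
                   stats::var(st[[oc]][ok]) > 0)
          stats::cor(rank(st[[mc]][ok]), rank(st[[oc]][ok])) else NA_real_
        n_used <- sum(ok)
        p_asy <- if (!is.na(rho) && abs(rho) < 1 && n_used > 2) {
          tt <- rho * sqrt((n_used - 2) / (1 - rho^2))
          2 * stats::pt(-abs(tt), df = n_used - 2)
        } else NA_real_
        cors[[length(cors) + 1L]] <- data.frame(
          cohort = co, tract = tr, metric = mc, outcome = oc,
          rho = rho, n_used = n_used, p_asymptotic = p_asy,
          stringsAsFactors = FALSE)
      }
    }
    # global TLV / TLC correlations
    for (mc in c("tlv_ml", "tlc")) for (oc in c("edss0", "delta_edss")) {
      ok <- is.finite(gsub[[mc]]) & is.finite(gsub[[oc]])
      rho <- if (sum(ok) >= 3L && stats::var(gsub[[mc]][ok]) > 0 &&
                 stats::var(gsub[[oc]][ok]) > 0)
        stats::cor(rank(gsub[[mc]][ok]), rank(gsub[[oc]][ok])) else NA_real_
      cors[[length(cors) + 1L]] <- data.frame(
        cohort = co, tract = "(global)", metric = mc, outcome = oc,
        rho = rho, n_used = sum(ok), p_asymptotic = NA_real_,
        stringsAsFactors = FALSE)
    }
    # comparison families with BH across tracts within each family
    seeds <- derive_seeds(master_seed + match(co, unique(outcomes$cohort)),
                          length(families) * length(tracts))
    si <- 0L
    for (fam in families) {
      fam_rows <- list()
      for (tr in tracts) {
        si <- si + 1L
        if (fam$lesion && !(tr %in% retained)) next
        st <- sub[sub$tract == tr, ]
        res <- tryCatch({
          if (fam$type == "metrics")
            permutation_compare_metrics(st[[fam$metric_A]],
                                        st[[fam$metric_B]],
                                        st[[fam$outcome]],
                                        n_perm = n_perm,
                                        sided = fam$sided,
                                        seed = seeds[si])
          else
            permutation_compare_outcomes(st[[fam$metric_A]],
                                         st$edss0, st$delta_edss,
                                         n_perm = n_perm,
                                         sided = fam$sided,
                                         seed = seeds[si])
        }, error = function(e) NULL)
        if (is.null(res)) next
        fam_rows[[tr]] <- data.frame(
          cohort = co, family = fam$id, tract = tr,
          rho_A = res$rho_A, rho_B = res$rho_B, d_obs = res$d_obs,
          sided = fam$sided, n_used = res$n_used, p_perm = res$p,
          stringsAsFactors = FALSE)
      }
      if (length(fam_rows)) {
        famdf <- do.call(rbind, fam_rows)
        famdf$p_adj <- bh_adjust(famdf$p_perm)
        comps[[length(comps) + 1L]] <- famdf
      }
    }
  }
  structure(list(correlations = do.call(rbind, cors),
                 comparisons = do.call(rbind, comps),
                 config = list(n_perm = n_perm, min_patients = min_patients,
                               bh_alpha = bh_alpha,
                               master_seed = master_seed)),
            class = "correlation_study")
}

#' @export
print.correlation_study <- function(x, ...) {
  cat(sprintf(paste0("Correlation study: %d correlations, %d permutation",
                     " comparisons (n_perm = %d)\n"),
              nrow(x$correlations), nrow(x$comparisons), x$config$n_perm))
  sig <- x$comparisons[!is.na(x$comparisons$p_adj) &
                         x$comparisons$p_adj < x$config$bh_alpha, ]
  cat(sprintf("  BH-significant comparisons at alpha = %.2f: %d\n",
              x$config$bh_alpha, nrow(sig)))
  if (nrow(sig)) {
    sig <- sig[order(sig$p_adj), ]
    print(utils::head(sig[, c("cohort", "family", "tract", "d_obs",
                              "p_perm", "p_adj")], 10), row.names = FALSE)
  }
  invisible(x)
}
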