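# Registration quality control via mutual information.
#
# MI is computed from the joint histogram of the registered anatomical
# image and the template, over an equal-width 2D binning of each image's
# masked min-max range.  Subjects whose MI falls strictly below the fifth
# percentile of the cohort's MI values are flagged for visual inspection.

bin_indices <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(list(idx = rep(1L, length(x)), nbins = 1L))
  idx <- pmin(bins, 1L + floor((x - lo) / (hi - lo) * bins))
  list(idx = as.integer(idx), nbins = as.integer(bins))
}

#' Joint histogram of two images
#'
#' Equal-width 2D binning of (a, b) within each image's masked min-max
#' range; the total count equals the number of masked voxels.  A constant
#' image degenerates to a single bin along its axis (with a warning).
#'
#' @param a,b `brain_volume`s (or arrays) on one grid.
#' @param bins number of bins per axis (>= 2).
#' @param mask optional `brain_mask`; defaults to all finite voxels.
#' @return integer matrix of counts (a-bins in rows, b-bins in columns).
#' @export
joint_histogram <- function(a, b, bins = 64, mask = NULL) {
  if (bins < 2) stop("bins must be >= 2")
  av <- vol_data(a); bv <- vol_data(b)
  if (!identical(dim(av), dim(bv))) stop("images are not on one grid")
  keep <- is.finite(av) & is.finite(bv)
  if (!is.null(mask)) keep <- keep & vol_data(mask)
  if (!any(keep)) stop("empty mask: no finite voxels to histogram")
  x <- av[keep]; y <- bv[keep]
  if (min(x) == max(x) || min(y) == max(y))
    warning("constant image: degenerate single-bin axis")
  ia <- bin_indices(x, bins); ib <- bin_indices(y, bins)
  counts <- tabulate((ib$idx - 1L) * ia$nbins + ia$idx,
                     nbins = ia$nbins * ib$nbins)
  matrix(counts, nrow = ia$nbins, ncol = ib$nbins)
}

#' Mutual information between two images
#'
#' MI = sum p(i,j) log(p(i,j) / (p(i) p(j))) over non-empty cells of the
#' normalized joint histogram.  Always >= 0 and symmetric; equals the
#' marginal entropy when the images are identical.
#'
#' @inheritParams joint_histogram
#' @param base `"e"` (nats, default) or `"2"` (bits).
#' @return scalar MI.
#' @export
mutual_information <- function(a, b, bins = 64, mask = NULL, base = c("e", "2")) {
  base <- match.arg(base)
  h <- joint_histogram(a, b, bins, mask)
  p <- h / sum(h)
  pi_ <- rowSums(p); pj <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  mi <- sum(p[nz] * log(p[nz] / (pi_[nz[, 1L]] * pj[nz[, 2L]])))
  mi <- max(mi, 0)  # clip tiny negative rounding residue
  if (base == "2") mi / log(2) else mi
}

#' Flag subjects with poor registration by cohort MI percentile
#'
#' The threshold is the configured percentile (default the fifth) of the
#' cohort's MI values, using linear interpolation between order
#' statistics; subjects with MI strictly below it are flagged for visual
#' inspection (a value exactly at the threshold passes).
#'
#' @param mi named numeric vector of per-subject MI values (>= 2 subjects).
#' @param percentile percentile in (0, 100).
#' @return data.frame with columns `subject_id`, `mi`, `flagged`,
#'   `threshold`.
#' @export
flag_outliers <- function(mi, percentile = 5) {
  if (length(mi) < 2L) stop("need >= 2 subjects to set a threshold")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  thr <- unname(stats::quantile(mi, percentile / 100, type = 7))
  ids <- if (is.null(names(mi))) sprintf("S%03d", seq_along(mi))
         else names(mi)
  data.frame(subject_id = ids, mi = unname(mi), flagged = unname(mi) < thr,
             threshold = thr, stringsAsFactors = FALSE)
}

#' Run MI-based registration QC over a cohort
#'
#' Computes each subject's MI against the template within the brain mask
#' and applies the percentile flagging rule over the whole cohort jointly.
#'
#' @param volumes named list (by subject id) of registered anatomical
#'   `brain_volume`s.
#' @param template template `brain_volume`.
#' @param mask optional `brain_mask`.
#' @param bins histogram bins per axis.
#' @param percentile flagging percentile.
#' @return data.frame as in [flag_outliers()]; attributes `bins` and
#'   `percentile` record the configuration.
#' @export
qc_cohort <- function(volumes, template, mask = NULL, bins = 64,
                      percentile = 5) {
  mi <- vapply(volumes, function(v)
    mutual_information(v, template, bins, mask), numeric(1L))
  out <- flag_outliers(mi, percentile)
  attr(out, "bins") <- bins
  attr(out, "percentile") <- percentile
  out
}
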