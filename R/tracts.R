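# Tract density maps -> binary tract masks.
#
# Fixed pipeline order: merge hemispheres (sum densities) -> normalize by
# the maximum -> binarize at a fraction of the peak (default 5%,
# inclusive >=).  Midline tracts pass through the merge step unchanged.

#' Construct a tract definition
#'
#' @param name full tract name.
#' @param abbreviation short code (e.g. CST, ILF, ICP).
#' @param density `brain_volume` of streamline density (unitless, >= 0).
#' @param tract_class one of projection, association, commissural,
#'   brainstem, cerebellar.
#' @param laterality one of left, right, merged, midline.
#' @return an object of class `tract_definition`.
#' @export
tract_definition <- function(name, abbreviation, density,
                             tract_class = c("projection", "association",
                                             "commissural", "brainstem",
                                             "cerebellar"),
                             laterality = c("left", "right", "merged",
                                            "midline")) {
  stopifnot(inherits(density, "brain_volume"))
  d <- vol_data(density)
  if (any(d[is.finite(d)] < 0)) stop("tract density must be >= 0")
  structure(list(name = as.character(name),
                 abbreviation = as.character(abbreviation),
                 density = density, mask = NULL,
                 tract_class = match.arg(tract_class),
                 laterality = match.arg(laterality)),
            class = "tract_definition")
}

#' @export
print.tract_definition <- function(x, ...) {
  cat(sprintf("<tract> %s (%s), %s, %s%s\n", x$abbreviation, x$name,
              x$tract_class, x$laterality,
              if (is.null(x$mask)) ""
              else sprintf(", mask %d voxels", sum(vol_data(x$mask)))))
  invisible(x)
}

#' Merge left/right hemispheric tract maps
#'
#' Density maps are summed voxel-wise; merging precedes normalization.
#' Midline/merged tracts pass through unchanged when `right` is `NULL`.
#'
#' @param left,right `tract_definition`s of the two hemispheres (same
#'   grid, same abbreviation).
#' @return a merged `tract_definition` (laterality `"merged"`).
#' @export
merge_hemispheres <- function(left, right = NULL) {
  stopifnot(inherits(left, "tract_definition"))
  if (is.null(right)) return(left)
  stopifnot(inherits(right, "tract_definition"))
  if (left$abbreviation != right$abbreviation)
    stop("cannot merge tracts with different abbreviations: ",
         left$abbreviation, " vs ", right$abbreviation)
  if (left$laterality == right$laterality)
    stop("cannot merge two '", left$laterality, "' tracts")
  stop_unless_same_grid(left$density, right$density, what = "tract densities")
  merged <- left
  merged$density <- brain_volume(vol_data(left$density) +
                                   vol_data(right$density),
                                 left$density$voxel_size,
                                 left$density$space)
  merged$laterality <- "merged"
  merged$mask <- NULL
  merged
}

#' Normalize a tract density map by its maximum
#'
#' @param t a `tract_definition` with max density > 0.
#' @return the tract with density divided by its maximum (max becomes 1).
#' @export
normalize_density <- function(t) {
  stopifnot(inherits(t, "tract_definition"))
  d <- vol_data(t$density)
  mx <- max(d[is.finite(d)])
  if (!is.finite(mx) || mx <= 0) stop("empty tract: all-zero density")
  t$density <- brain_volume(d / mx, t$density$voxel_size, t$density$space)
  t
}

#' Binarize a normalized density map
#'
#' Voxels with density >= `threshold` (inclusive) enter the mask; the
#' default 0.05 discards voxels with low streamline density.  The peak
#' voxel always survives, so the mask is never empty.
#'
#' @param t a `tract_definition` whose density is normalized (max = 1).
#' @param threshold fraction of the peak, in (0, 1].
#' @return the tract with its `mask` field set (`brain_mask`).
#' @export
binarize_density <- function(t, threshold = 0.05) {
  stopifnot(inherits(t, "tract_definition"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  d <- vol_data(t$density)
  mx <- max(d[is.finite(d)])
  if (abs(mx - 1) > 1e-8)
    stop("density must be normalized (max = 1) before binarization; ",
         "call normalize_density() first")
  m <- is.finite(d) & d >= threshold
  t$mask <- brain_mask(m, t$density$voxel_size, t$density$space)
  t
}

#' Load a tract atlas from a directory of density maps + TSV manifest
#'
#' The manifest must have columns `file`, `abbreviation`, `name`, `class`,
#' `laterality`; files are NIfTI density maps relative to `dir`.
#'
#' @param dir directory containing the maps.
#' @param manifest path to the TSV manifest (default `dir/tracts.tsv`).
#' @param space space tag for the loaded volumes.
#' @return list of `tract_definition`s.
#' @export
load_tract_atlas <- function(dir, manifest = file.path(dir, "tracts.tsv"),
                             space = "template") {
  if (!file.exists(manifest)) stop("tract manifest not found: ", manifest)
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  req <- c("file", "abbreviation", "name", "class", "laterality")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("tract manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    tract_definition(tab$name[i], tab$abbreviation[i],
                     read_volume(file.path(dir, tab$file[i]), space),
                     tab$class[i], tab$laterality[i]))
}

#' Build final binary tract masks: merge -> normalize -> binarize
#'
#' Left/right pairs (matched by abbreviation) are merged first; each
#' merged map is normalized by its maximum and binarized at `threshold`.
#' When a brain mask is given, tract masks are intersected with it so
#' NaN z-scores never enter metric summaries.
#'
#' @param tracts list of `tract_definition`s (any lateralities).
#' @param threshold binarization fraction of the peak (default 0.05).
#' @param brain_mask optional `brain_mask` to intersect with.
#' @return named list (by abbreviation) of `tract_definition`s with masks.
#' @export
build_tract_masks <- function(tracts, threshold = 0.05, brain_mask = NULL) {
  abbr <- vapply(tracts, `[[`, "", "abbreviation")
  out <- lapply(split(seq_along(abbr), factor(abbr, levels = unique(abbr))),
                function(ix) {
    grp <- tracts[ix]
    if (length(grp) == 1L) {
      merged <- merge_hemispheres(grp[[1L]])
    } else if (length(grp) == 2L) {
      merged <- merge_hemispheres(grp[[1L]], grp[[2L]])
    } else {
      stop("tract ", grp[[1L]]$abbreviation,
           " has more than two lateralized maps")
    }
    t <- binarize_density(normalize_density(merged), threshold)
    if (!is.null(brain_mask)) {
      stop_unless_same_grid(t$mask, brain_mask,
                            what = "tract mask and brain mask")
      t$mask <- brain_mask(vol_data(t$mask) & vol_data(brain_mask),
                           t$mask$voxel_size, t$mask$space)
    }
    t
  })
  names(out) <- unique(abbr)
  out
}
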