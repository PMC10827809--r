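# Voxel-wise normative T1 model.
#
# At every brain voxel v, the expected T1 of a healthy subject is
#   E{T1}(v) = beta0(v) + beta_sex(v)*sex + beta_age(v)*a + beta_age2(v)*a^2
# with a = age - center_age (age centered at the healthy-cohort mean) and
# sex coded 1 = male, 0 = female.  Coefficients are ordinary least
# squares per voxel; the residual SD uses the unbiased denominator n - 4
# and is floored at sigma_floor.  Patient deviations are reported as
# z(v) = (T1(v) - E{T1}(v)) / sigma(v).

#' Fit the voxel-wise normative T1 model
#'
#' One shared design matrix `[1, sex, a, a^2]` is fitted by QR least
#' squares simultaneously at every voxel inside the brain mask.  No
#' spatial regularisation or smoothing is applied: the fit is purely
#' voxel-wise.
#'
#' @param cohort list of [subject_record()]s with T1 volumes attached
#'   (n >= 5: four coefficients plus at least one degree of freedom for
#'   the variance).
#' @param brain_mask `brain_mask` restricting the fit; voxels outside are
#'   NaN in every output map.
#' @param center_age age-centering constant in years; defaults to the
#'   cohort mean age.
#' @param sigma_floor lower bound on the residual SD map in ms (guards
#'   against division blow-ups in degenerate data); a message is emitted
#'   when the floor is applied.
#' @return an object of class `normative_model`.
#' @export
fit_normative_model <- function(cohort, brain_mask, center_age = NULL,
                                sigma_floor = 1) {
  n <- length(cohort)
  if (n < 5L)
    stop("insufficient degrees of freedom: need >= 5 subjects, got ", n)
  stopifnot(inherits(brain_mask, "brain_mask"), sigma_floor > 0)
  vols <- lapply(cohort, `[[`, "t1")
  if (any(vapply(vols, is.null, logical(1L))))
    stop("every subject needs a T1 volume attached")
  if (!check_same_grid(c(vols, list(brain_mask))))
    stop("cohort T1 maps and brain mask are not on one grid")
  ages <- vapply(cohort, `[[`, numeric(1L), "age")
  sexes <- vapply(cohort, `[[`, numeric(1L), "sex")
  if (is.null(center_age)) center_age <- mean(ages)
  a <- ages - center_age
  X <- cbind(intercept = 1, sex = sexes, age = a, age2 = a^2)
  if (qr(X)$rank < 4L) {
    degenerate <- if (stats::var(sexes) == 0) "sex" else "age"
    stop("rank-deficient design: degenerate covariate '", degenerate, "'")
  }
  mask_arr <- vol_data(brain_mask)
  midx <- which(mask_arr)
  Y <- vapply(vols, function(v) v$data[midx], numeric(length(midx)))
  fit <- stats::lm.fit(X, t(Y))
  B <- fit$coefficients                      # 4 x V
  rss <- colSums(fit$residuals^2)
  sig <- sqrt(rss / (n - 4))
  n_floored <- sum(sig < sigma_floor)
  if (n_floored > 0)
    message("sigma floored at ", sigma_floor, " ms in ", n_floored,
            " voxel(s)")
  sig <- pmax(sig, sigma_floor)
  grid <- dim(mask_arr)
  as_map <- function(vals) {
    m <- array(NaN, dim = grid)
    m[midx] <- vals
    brain_volume(m, brain_mask$voxel_size, brain_mask$space)
  }
  structure(list(beta0 = as_map(B[1L, ]), beta_sex = as_map(B[2L, ]),
                 beta_age = as_map(B[3L, ]), beta_age2 = as_map(B[4L, ]),
                 sigma = as_map(sig), center_age = center_age,
                 n_train = n, sigma_floor = sigma_floor,
                 n_sigma_floored = n_floored,
                 brain_mask = brain_mask),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(paste0("Voxel-wise normative T1 model\n",
                     "  trained on n = %d subjects, age centered at %.1f y\n",
                     "  %d brain voxels (%s grid), sigma floor %g ms",
                     " (%d voxel(s) floored)\n"),
              x$n_train, x$center_age, sum(vol_data(x$brain_mask)),
              paste(dim(vol_data(x$brain_mask)), collapse = "x"),
              x$sigma_floor, x$n_sigma_floored))
  invisible(x)
}

#' @export
summary.normative_model <- function(object, ...) {
  maps <- c("beta0", "beta_sex", "beta_age", "beta_age2", "sigma")
  qs <- t(vapply(maps, function(m) {
    v <- vol_data(object[[m]])
    stats::quantile(v[is.finite(v)], c(0, 0.25, 0.5, 0.75, 1))
  }, numeric(5L)))
  colnames(qs) <- c("min", "q25", "median", "q75", "max")
  out <- list(model = object, coefficient_quantiles = qs)
  class(out) <- "summary.normative_model"
  out
}

#' @export
print.summary.normative_model <- function(x, ...) {
  print(x$model)
  cat("\nCoefficient map quantiles (ms; slopes ms/y, ms/y^2):\n")
  print(round(x$coefficient_quantiles, 4))
  invisible(x)
}

#' @export
coef.normative_model <- function(object, ...) {
  list(beta0 = object$beta0, beta_sex = object$beta_sex,
       beta_age = object$beta_age, beta_age2 = object$beta_age2)
}

#' Predict the normative T1 map for given covariates
#'
#' @param object a `normative_model`.
#' @param age age in years.
#' @param sex 1 = male, 0 = female.
#' @param ... unused.
#' @return `brain_volume` of expected T1 (ms), NaN outside the brain mask.
#' @export
predict.normative_model <- function(object, age, sex, ...) {
  a <- age - object$center_age
  sex <- parse_sex(sex)
  pred <- vol_data(object$beta0) + sex * vol_data(object$beta_sex) +
    a * vol_data(object$beta_age) + a^2 * vol_data(object$beta_age2)
  brain_volume(pred, object$brain_mask$voxel_size, object$brain_mask$space)
}

#' Simulate healthy T1 maps from a fitted normative model
#'
#' @param object a `normative_model`.
#' @param nsim number of maps.
#' @param seed optional seed.
#' @param age,sex covariates for all draws.
#' @param ... unused.
#' @return list of `brain_volume`s.
#' @export
simulate.normative_model <- function(object, nsim = 1, seed = NULL,
                                     age = object$center_age, sex = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- vol_data(predict(object, age, sex))
  sig <- vol_data(object$sigma)
  lapply(seq_len(nsim), function(i) {
    eps <- array(stats::rnorm(length(mu)), dim = dim(mu)) * sig
    brain_volume(mu + eps, object$brain_mask$voxel_size,
                 object$brain_mask$space)
  })
}

#' @export
plot.normative_model <- function(x, slice = NULL, ...) {
  b0 <- vol_data(x$beta0); sg <- vol_data(x$sigma)
  if (is.null(slice)) slice <- ceiling(dim(b0)[3L] / 2)
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(b0[, , slice], main = sprintf("beta0 (z=%d)", slice),
                  col = grDevices::hcl.colors(64), asp = 1)
  graphics::image(sg[, , slice], main = "sigma", col =
                    grDevices::hcl.colors(64, "Reds", rev = TRUE), asp = 1)
  invisible(x)
}

#' Compute a patient z-score map
#'
#' z(v) = (T1(v) - E{T1}(v)) / sigma(v) inside the brain mask, NaN
#' outside.  Lesional voxels are not excluded: z metrics are later read
#' out both in NAWM and in lesions.
#'
#' @param model a fitted `normative_model`.
#' @param t1 patient T1 map (`brain_volume`, same grid as the model).
#' @param age,sex patient covariates.
#' @return `brain_volume` of z-scores (unitless).
#' @export
zscore_map <- function(model, t1, age, sex) {
  stopifnot(inherits(model, "normative_model"),
            inherits(t1, "brain_volume"))
  stop_unless_same_grid(t1, model$brain_mask,
                        what = "patient T1 and model")
  pred <- vol_data(predict(model, age, sex))
  z <- (vol_data(t1) - pred) / vol_data(model$sigma)
  z[!vol_data(model$brain_mask)] <- NaN
  brain_volume(z, t1$voxel_size, t1$space)
}

#' Persist a normative model as NIfTI maps + JSON sidecar
#'
#' @param model a `normative_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_normative_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in c("beta0", "beta_sex", "beta_age", "beta_age2", "sigma"))
    write_volume(model[[m]], file.path(dir, paste0(m, ".nii.gz")))
  write_volume(model$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  jsonlite::write_json(list(center_age = model$center_age,
                            n_train = model$n_train,
                            sigma_floor = model$sigma_floor,
                            n_sigma_floored = model$n_sigma_floored,
                            space = model$brain_mask$space),
                       file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a persisted normative model
#'
#' @param dir directory written by [write_normative_model()].
#' @return a `normative_model`.
#' @export
read_normative_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  maps <- lapply(c(beta0 = "beta0", beta_sex = "beta_sex",
                   beta_age = "beta_age", beta_age2 = "beta_age2",
                   sigma = "sigma"),
                 function(m) read_volume(file.path(dir, paste0(m, ".nii.gz")),
                                         space = meta$space))
  bm <- read_mask(file.path(dir, "brain_mask.nii.gz"), space = meta$space)
  structure(c(maps, list(center_age = meta$center_age,
                         n_train = meta$n_train,
                         sigma_floor = meta$sigma_floor,
                         n_sigma_floored = meta$n_sigma_floored,
                         brain_mask = bm)),
            class = "normative_model")
}
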