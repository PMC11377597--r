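#' Fit the voxelwise age + TIV normative grey-matter model
#'
#' For every voxel inside the fit mask, ordinary least squares of the
#' control grey-matter value on an intercept, age and total intracranial
#' volume. The per-voxel residual SD uses the unbiased n - 3 denominator.
#' Covariates are centred and scaled internally for conditioning; w-scores
#' are invariant to that choice, and [coef()] reports coefficients on the
#' original scale (GM units per year, per mL).
#'
#' The fitted object is the package's central model: athlete maps are
#' scored against it with [wscore_map()] (or `predict(..., type =
#' "wscore")`), giving covariate-adjusted z-scores in units of the
#' controls' residual SD. Lower w means lower grey matter than expected
#' for age and head size.
#'
#' @param gm list of control grey-matter `image_volume`s.
#' @param subjects data.frame with `age` (years) and `tiv` (mL), one row
#'   per volume, plus optional `subject_id` (duplicates rejected).
#' @param fit_mask logical array or `image_volume`; voxels to fit
#'   (default: all voxels).
#' @param sd_floor voxels with residual SD below this (GM units) are
#'   flagged and excluded from downstream summaries.
#' @return An object of class `normative_model`.
#' @export
fit_normative <- function(gm, subjects, fit_mask = NULL, sd_floor = 1e-6) {
  n <- length(gm)
  if (n < 10L) stop("fit_normative: need at least 10 controls, got ", n)
  if (nrow(subjects) != n)
    stop("fit_normative: ", n, " volumes but ", nrow(subjects), " subject rows")
  if ("subject_id" %in% names(subjects) && anyDuplicated(subjects$subject_id))
    stop("fit_normative: duplicate subjects in the control set")
  for (i in seq_len(n)[-1]) assert_same_grid(gm[[1]], gm[[i]])
  d <- dim(gm[[1]]$data)
  mask <- if (is.null(fit_mask)) array(TRUE, dim = d) else as_mask(fit_mask)
  if (!identical(dim(mask), d)) stop("fit_normative: fit_mask grid mismatch")
  age <- as.numeric(subjects$age); tiv <- as.numeric(subjects$tiv)
  for (nmv in c("age", "tiv")) {
    v <- get(nmv)
    if (anyNA(v)) stop("fit_normative: missing ", nmv, " in control table")
    if (stats::sd(v) < 1e-12)
      stop("fit_normative: degenerate covariate '", nmv, "' (constant across controls)")
  }
  scaling <- list(age_mean = mean(age), age_sd = stats::sd(age),
                  tiv_mean = mean(tiv), tiv_sd = stats::sd(tiv))
  X <- cbind(1, (age - scaling$age_mean) / scaling$age_sd,
             (tiv - scaling$tiv_mean) / scaling$tiv_sd)
  qrx <- qr(X)
  if (qrx$rank < 3L)
    stop("fit_normative: rank-deficient design (age and TIV collinear)")
  vox <- which(mask)
  Y <- matrix(NA_real_, n, length(vox))
  for (i in seq_len(n)) Y[i, ] <- gm[[i]]$data[vox]
  if (anyNA(Y)) stop("fit_normative: missing voxel values inside the fit mask")
  beta <- qr.coef(qrx, Y)                    # 3 x V, scaled covariates
  resid <- Y - X %*% beta
  resid_sd <- sqrt(colSums(resid^2) / (n - 3))
  structure(list(beta = beta, resid_sd = resid_sd, vox = vox, dims = d,
                 voxel_size_mm = gm[[1]]$voxel_size_mm, space = gm[[1]]$space,
                 fit_mask = mask, n_controls = n, scaling = scaling,
                 age_range = range(age), tiv_range = range(tiv),
                 sd_floor = sd_floor),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> voxelwise GM ~ age + TIV, %d controls\n", x$n_controls))
  cat(sprintf("  grid %s, %d voxels in fit mask\n",
              paste(x$dims, collapse = "x"), length(x$vox)))
  cat(sprintf("  control age %.1f-%.1f y, TIV %.0f-%.0f mL\n",
              x$age_range[1], x$age_range[2], x$tiv_range[1], x$tiv_range[2]))
  cat(sprintf("  residual SD: median %.4g, %d voxel(s) below floor %.1g\n",
              stats::median(x$resid_sd), sum(x$resid_sd < x$sd_floor), x$sd_floor))
  invisible(x)
}

#' @export
summary.normative_model <- function(object, ...) {
  co <- stats::coef(object)
  out <- list(
    n_controls = object$n_controls,
    n_voxels = length(object$vox),
    n_below_sd_floor = sum(object$resid_sd < object$sd_floor),
    beta_age = summary(co["age", ]),
    beta_tiv = summary(co["tiv", ]),
    resid_sd = summary(object$resid_sd),
    age_range = object$age_range, tiv_range = object$tiv_range)
  class(out) <- "summary.normative_model"
  out
}

#' @export
print.summary.normative_model <- function(x, ...) {
  cat(sprintf("Voxelwise normative model: %d controls, %d voxels (%d below SD floor)\n",
              x$n_controls, x$n_voxels, x$n_below_sd_floor))
  cat("beta_age (GM units / year):\n"); print(x$beta_age)
  cat("beta_tiv (GM units / mL):\n"); print(x$beta_tiv)
  cat("residual SD (GM units):\n"); print(x$resid_sd)
  invisible(x)
}

#' Per-voxel coefficients on the original covariate scale
#'
#' @param object a `normative_model`.
#' @param ... unused.
#' @return Matrix with rows `intercept`, `age`, `tiv` and one column per
#'   fitted voxel.
#' @export
coef.normative_model <- function(object, ...) {
  s <- object$scaling
  b_age <- object$beta[2, ] / s$age_sd
  b_tiv <- object$beta[3, ] / s$tiv_sd
  b0 <- object$beta[1, ] - b_age * s$age_mean - b_tiv * s$tiv_mean
  rbind(intercept = b0, age = b_age, tiv = b_tiv)
}

# internal: predicted GM values at the fitted voxels for given covariates
.predict_vox <- function(model, age, tiv) {
  s <- model$scaling
  x <- c(1, (age - s$age_mean) / s$age_sd, (tiv - s$tiv_mean) / s$tiv_sd)
  as.numeric(crossprod(model$beta, x))
}

#' Predict from a normative model
#'
#' `type = "volume"` returns the expected grey-matter map for the given
#' age/TIV; `type = "wscore"` scores an observed map (see [wscore_map()]).
#'
#' @param object a `normative_model`.
#' @param age,tiv subject covariates.
#' @param type `"volume"` or `"wscore"`.
#' @param gm observed `image_volume` (required for `type = "wscore"`).
#' @param ... passed to [wscore_map()].
#' @return An `image_volume`.
#' @export
predict.normative_model <- function(object, age, tiv, type = c("volume", "wscore"),
                                    gm = NULL, ...) {
  type <- match.arg(type)
  if (type == "wscore") {
    if (is.null(gm)) stop("predict: type = 'wscore' requires the observed gm volume")
    return(wscore_map(object, gm, age, tiv, ...))
  }
  out <- array(NA_real_, dim = object$dims)
  out[object$vox] <- .predict_vox(object, age, tiv)
  image_volume(out, object$voxel_size_mm, object$space)
}

#' Simulate control-like grey-matter maps from a fitted normative model
#'
#' Draws `predicted + N(0, resid_sd)` voxelwise for the given covariates.
#'
#' @param object a `normative_model`.
#' @param nsim number of maps.
#' @param seed RNG seed.
#' @param age,tiv covariates, recycled to `nsim`.
#' @param ... unused.
#' @return List of `image_volume`s.
#' @export
simulate.normative_model <- function(object, nsim = 1, seed = NULL,
                                     age, tiv, ...) {
  if (!is.null(seed)) set.seed(seed)
  age <- rep_len(age, nsim); tiv <- rep_len(tiv, nsim)
  lapply(seq_len(nsim), function(i) {
    mu <- .predict_vox(object, age[i], tiv[i])
    out <- array(NA_real_, dim = object$dims)
    out[object$vox] <- mu + stats::rnorm(length(mu), 0, object$resid_sd)
    image_volume(out, object$voxel_size_mm, object$space)
  })
}

#' Compute a subject's w-score map
#'
#' Per voxel inside the fit mask:
#' `w = (observed - (b0 + b_age * age + b_tiv * tiv)) / resid_sd`.
#' Voxels whose control residual SD falls below the model's floor are set
#' missing. Covariates outside the control range (widened by
#' `guard_frac` of the range per side) trigger an extrapolation warning,
#' never a silent score.
#'
#' @param model a [fit_normative()] model.
#' @param gm observed grey-matter `image_volume` on the model grid.
#' @param age,tiv subject covariates (years, mL).
#' @param guard_frac extrapolation guard band as a fraction of the control
#'   covariate range.
#' @return w-score `image_volume` (`NA` outside the fit mask).
#' @export
wscore_map <- function(model, gm, age, tiv, guard_frac = 0.1) {
  stopifnot(inherits(model, "normative_model"), inherits(gm, "image_volume"))
  if (!identical(dim(gm$data), model$dims))
    stop("wscore_map: grid mismatch: ", paste(dim(gm$data), collapse = "x"),
         " vs model ", paste(model$dims, collapse = "x"))
  if (any(abs(gm$voxel_size_mm - model$voxel_size_mm) > 1e-3))
    stop("wscore_map: voxel size mismatch with model grid")
  for (v in list(c("age", age, model$age_range), c("tiv", tiv, model$tiv_range))) {
    nmv <- v[1]; val <- as.numeric(v[2]); rng <- as.numeric(v[3:4])
    band <- guard_frac * diff(rng)
    if (val < rng[1] - band || val > rng[2] + band)
      warning("wscore_map: ", nmv, " = ", signif(val, 4),
              " outside control range [", signif(rng[1], 4), ", ",
              signif(rng[2], 4), "] (extrapolation)")
  }
  pred <- .predict_vox(model, age, tiv)
  w <- (gm$data[model$vox] - pred) / model$resid_sd
  w[model$resid_sd < model$sd_floor] <- NA_real_
  out <- array(NA_real_, dim = model$dims)
  out[model$vox] <- w
  image_volume(out, model$voxel_size_mm, model$space)
}

#' Mean w-scores over the tau-positive and tau-negative masks
#'
#' Averages a subject's w-score map over two disjoint masks (typically the
#' tau-PET positive and negative grey-matter masks). Missing voxels are
#' excluded; an empty positive mask yields a missing positive mean (the
#' subject is retained and the paired analysis drops it later).
#'
#' @param w w-score `image_volume`.
#' @param positive_mask,negative_mask logical arrays (or `image_volume`s);
#'   must not overlap.
#' @return `list(mean_w_pos, mean_w_neg, n_vox_pos, n_vox_neg)` of class
#'   `wscore_summary`.
#' @export
extract_mask_means <- function(w, positive_mask, negative_mask) {
  pm <- as_mask(positive_mask); nm <- as_mask(negative_mask)
  if (!identical(dim(pm), dim(w$data)) || !identical(dim(nm), dim(w$data)))
    stop("extract_mask_means: mask grid mismatch")
  if (any(pm & nm)) stop("extract_mask_means: masks overlap")
  mean_of <- function(m) {
    v <- w$data[m]; v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  structure(list(mean_w_pos = mean_of(pm), mean_w_neg = mean_of(nm),
                 n_vox_pos = sum(pm & !is.na(w$data)),
                 n_vox_neg = sum(nm & !is.na(w$data))),
            class = "wscore_summary")
}

#' @export
print.wscore_summary <- function(x, ...) {
  cat(sprintf("<wscore_summary> mean w: tau+ %.4g (%d vox), tau- %.4g (%d vox)\n",
              x$mean_w_pos, x$n_vox_pos, x$mean_w_neg, x$n_vox_neg))
  invisible(x)
}
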