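#' Scanner-specific PET smoothing kernels
#'
#' FWHM triples (mm) that equalize the effective spatial resolution of the
#' two PET scanners: 6.55 x 6.55 x 7.75 mm for the Biograph PET/CT and
#' 7.37 x 7.37 x 7.91 mm for the HRRT.
#'
#' @param scanner `"PETCT"` or `"HRRT"`.
#' @return Numeric FWHM triple (x, y, z) in mm.
#' @export
smoothing_kernel <- function(scanner = c("PETCT", "HRRT")) {
  scanner <- match.arg(scanner)
  switch(scanner,
         PETCT = c(6.55, 6.55, 7.75),
         HRRT = c(7.37, 7.37, 7.91))
}

#' Duration-weighted average of PET time frames
#'
#' Averages the frames intersecting the reconstruction window (e.g.
#' 80--100 or 80--90 min post-injection), each weighted by its overlap
#' duration with the window. Frames must be sorted and non-overlapping and
#' must cover the window.
#'
#' @param frames list of `list(vol = image_volume, start = min, end = min)`.
#' @param window numeric `c(t0, t1)` in minutes.
#' @param weighted if `FALSE`, intersecting frames are averaged unweighted.
#' @return An `image_volume`.
#' @export
average_frames <- function(frames, window, weighted = TRUE) {
  stopifnot(length(window) == 2L, window[1] < window[2], length(frames) >= 1L)
  starts <- vapply(frames, `[[`, numeric(1), "start")
  ends <- vapply(frames, `[[`, numeric(1), "end")
  if (is.unsorted(starts) || any(starts[-1] < ends[-length(ends)] - 1e-9))
    stop("average_frames: frames must be sorted and non-overlapping")
  # coverage check over the window
  t <- window[1]
  for (i in seq_along(frames)) {
    if (ends[i] <= t + 1e-9) next
    if (starts[i] > t + 1e-9)
      stop(sprintf("average_frames: window [%g, %g] not covered; gap at [%g, %g]",
                   window[1], window[2], t, min(starts[i], window[2])))
    t <- min(ends[i], window[2])
    if (t >= window[2] - 1e-9) break
  }
  if (t < window[2] - 1e-9)
    stop(sprintf("average_frames: window [%g, %g] not covered; gap at [%g, %g]",
                 window[1], window[2], t, window[2]))
  w <- pmax(0, pmin(ends, window[2]) - pmax(starts, window[1]))
  use <- which(w > 1e-9)
  if (!weighted) w[use] <- 1
  for (i in use[-1]) assert_same_grid(frames[[use[1]]]$vol, frames[[i]]$vol)
  acc <- array(0, dim = dim(frames[[use[1]]]$vol$data))
  for (i in use) acc <- acc + w[i] * frames[[i]]$vol$data
  image_volume(acc / sum(w[use]), frames[[use[1]]]$vol$voxel_size_mm,
               frames[[use[1]]]$vol$space)
}

#' Compute an SUVR image against a reference region
#'
#' Divides every voxel by the mean activity over the reference-region mask
#' (inferior cerebellar grey matter in the source protocol).
#'
#' @param activity `image_volume` of (frame-averaged) PET activity.
#' @param reference_mask `image_volume` or logical array; nonempty, same grid.
#' @return SUVR `image_volume`.
#' @export
compute_suvr <- function(activity, reference_mask) {
  if (inherits(reference_mask, "image_volume"))
    assert_same_grid(activity, reference_mask)
  m <- as_mask(reference_mask)
  if (!identical(dim(m), dim(activity$data)))
    stop("compute_suvr: reference mask grid mismatch")
  vals <- activity$data[m]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("compute_suvr: empty reference mask")
  ref <- mean(vals)
  if (ref <= 0) stop("compute_suvr: reference mean is ", signif(ref, 4), " (<= 0)")
  image_volume(activity$data / ref, activity$voxel_size_mm, activity$space)
}

# 1-D Gaussian kernel matrix for one axis, with boundary handling.
.axis_kernel <- function(n, sigma_vox, boundary) {
  if (sigma_vox <= 0) return(diag(n))
  h <- max(1L, ceiling(3.5 * sigma_vox))
  w <- stats::dnorm(seq(-h, h), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - h):(i + h)
    keep <- j >= 1 & j <= n
    K[i, j[keep]] <- w[keep]
    if (boundary == "renorm") K[i, ] <- K[i, ] / sum(K[i, ])
    # "zero": truncated weights, implicit zeros outside the volume (SPM-style)
  }
  K
}

#' Separable Gaussian smoothing of a volume
#'
#' Convolves with an anisotropic Gaussian specified in mm FWHM; per-axis
#' sigma is `fwhm / (voxel_size * sqrt(8 ln 2))` voxels. At the volume
#' boundary (and at missing/out-of-mask voxels) the truncated kernel is
#' renormalized over its in-support weights, so constants are preserved
#' and edge voxels are not attenuated; SPM-style zero padding is available
#' via `boundary = "zero"`.
#'
#' @param vol `image_volume`.
#' @param fwhm_mm FWHM triple (x, y, z) in mm, each > 0 (0 = no smoothing
#'   on that axis).
#' @param boundary `"renorm"` (default) or `"zero"`.
#' @param mask optional logical array: voxels outside it are treated as
#'   missing and excluded from every kernel's support; output is `NA`
#'   outside the mask.
#' @return Smoothed `image_volume`.
#' @export
smooth_volume <- function(vol, fwhm_mm, boundary = c("renorm", "zero"), mask = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(vol, "image_volume"), length(fwhm_mm) == 3L, all(fwhm_mm >= 0))
  sig <- fwhm_mm / (vol$voxel_size_mm * sqrt(8 * log(2)))
  d <- dim(vol$data)
  A <- vol$data
  na <- is.na(A)
  if (!is.null(mask)) na <- na | !as_mask(mask)
  Kx <- .axis_kernel(d[1], sig[1], "zero")
  Ky <- .axis_kernel(d[2], sig[2], "zero")
  Kz <- .axis_kernel(d[3], sig[3], "zero")
  sep_apply <- function(X) {
    X <- array(Kx %*% matrix(X, d[1], d[2] * d[3]), dim = d)
    X <- aperm(X, c(2, 1, 3))
    X <- array(Ky %*% matrix(X, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    X <- aperm(X, c(2, 1, 3))
    X <- aperm(X, c(3, 2, 1))
    X <- array(Kz %*% matrix(X, d[3], d[2] * d[1]), dim = c(d[3], d[2], d[1]))
    aperm(X, c(3, 2, 1))
  }
  Az <- A; Az[na] <- 0
  num <- sep_apply(Az)
  if (boundary == "renorm" || any(na)) {
    sup <- array(1, dim = d); sup[na] <- 0
    den <- sep_apply(sup)
    if (boundary == "renorm") {
      out <- ifelse(den > 1e-12, num / den, NA_real_)
    } else {
      out <- num                      # zero padding: keep truncated normalization
      out[na] <- NA_real_
    }
  } else {
    out <- num
  }
  out[na] <- NA_real_
  image_volume(out, vol$voxel_size_mm, vol$space)
}

#' Threshold an SUVR image into tau-positive / tau-negative masks
#'
#' Positive voxels are grey-matter voxels whose SUVR meets the threshold
#' (default 1.30, comparator `">="`); the remaining grey-matter voxels are
#' negative. The two masks partition the grey-matter mask. `NA` voxels are
#' excluded from both masks.
#'
#' @param suvr SUVR `image_volume`.
#' @param gm_mask grey-matter mask (`image_volume` or logical array).
#' @param threshold SUVR threshold (default 1.30).
#' @param cmp `">="` (default) or `">"`; affects only exact-boundary voxels.
#' @return Object of class `positivity_result`: `positive_mask`,
#'   `negative_mask` (logical arrays), `threshold`, `cmp`, `n_gm`.
#' @export
threshold_positivity <- function(suvr, gm_mask, threshold = 1.30, cmp = c(">=", ">")) {
  cmp <- match.arg(cmp)
  if (inherits(gm_mask, "image_volume")) assert_same_grid(suvr, gm_mask)
  gm <- as_mask(gm_mask)
  if (!identical(dim(gm), dim(suvr$data)))
    stop("threshold_positivity: mask grid mismatch")
  gm <- gm & !is.na(suvr$data)
  if (!any(gm)) stop("threshold_positivity: empty grey-matter mask")
  hit <- if (cmp == ">=") suvr$data >= threshold else suvr$data > threshold
  hit[is.na(hit)] <- FALSE
  pos <- gm & hit
  structure(list(positive_mask = pos, negative_mask = gm & !pos,
                 threshold = threshold, cmp = cmp, n_gm = sum(gm)),
            class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  cat(sprintf("<positivity_result> threshold %s %.3g SUVR: %d / %d GM voxels positive (%.2f%%)\n",
              x$cmp, x$threshold, sum(x$positive_mask), x$n_gm,
              100 * sum(x$positive_mask) / x$n_gm))
  invisible(x)
}

#' Percent tau positivity, globally and per atlas region
#'
#' `100 * |positive voxels in region| / |grey-matter voxels in region|`.
#' Regions without grey-matter voxels get `NA` (reported, never silently
#' dropped).
#'
#' @param result a [threshold_positivity()] result.
#' @param atlas optional [label_atlas()] for per-region percentages.
#' @return `list(global = %, by_region = named numeric or NULL,
#'   n_pos_by_region, n_gm_by_region)`.
#' @export
percent_positivity <- function(result, atlas = NULL) {
  stopifnot(inherits(result, "positivity_result"))
  gm <- result$positive_mask | result$negative_mask
  out <- list(global = 100 * sum(result$positive_mask) / sum(gm),
              by_region = NULL, n_pos_by_region = NULL, n_gm_by_region = NULL)
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "label_atlas"))
    if (!identical(dim(atlas$labels), dim(gm)))
      stop("percent_positivity: atlas grid mismatch")
    labs <- sort(unique(atlas$labels[atlas$labels > 0L]))
    nm <- atlas$name_table[as.character(labs)]
    n_gm <- n_pos <- stats::setNames(integer(length(labs)), nm)
    pct <- stats::setNames(rep(NA_real_, length(labs)), nm)
    for (k in seq_along(labs)) {
      reg <- atlas$labels == labs[k]
      n_gm[k] <- sum(gm & reg)
      n_pos[k] <- sum(result$positive_mask & reg)
      if (n_gm[k] > 0L) pct[k] <- 100 * n_pos[k] / n_gm[k]
    }
    out$by_region <- pct; out$n_pos_by_region <- n_pos; out$n_gm_by_region <- n_gm
  }
  out
}
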