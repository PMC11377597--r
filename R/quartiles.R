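#' Assign subjects to % positivity quartile groups
#'
#' Rank-based split of the cohort into four ordered groups; quartile 1
#' holds the lowest % positivity values, quartile 4 the highest. When n is
#' not divisible by 4 the larger groups go to the lower quartiles. Ties in
#' % positivity are broken by stable subject-id order and reported.
#'
#' @param pct per-subject global % positivity.
#' @param ids subject identifiers (defaults to names or index).
#' @return Object of class `quartile_assignment`: `data.frame`
#'   (`subject_id`, `pct`, `quartile`), interior `cut_values`, group
#'   `sizes`, and `tied` flag.
#' @export
assign_quartiles <- function(pct, ids = NULL) {
  n <- length(pct)
  if (n < 4L) stop("assign_quartiles: need at least 4 subjects, got ", n)
  if (anyNA(pct)) stop("assign_quartiles: missing % positivity values")
  if (is.null(ids)) ids <- if (!is.null(names(pct))) names(pct) else as.character(seq_len(n))
  ord <- order(pct, ids)                       # stable tie-break by id
  sizes <- rep(n %/% 4L, 4L)
  rem <- n %% 4L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  q <- rep(rep(1:4, times = sizes), length.out = n)
  quartile <- integer(n)
  quartile[ord] <- q
  tied <- anyDuplicated(pct) > 0L
  if (tied)
    message("assign_quartiles: tied % positivity values; ties broken by subject-id order")
  cuts <- vapply(1:3, function(k) {
    lo <- max(pct[quartile == k]); hi <- min(pct[quartile == k + 1L])
    (lo + hi) / 2
  }, numeric(1))
  structure(list(assignment = data.frame(subject_id = ids, pct = pct,
                                         quartile = quartile,
                                         stringsAsFactors = FALSE),
                 cut_values = cuts, sizes = sizes, tied = tied),
            class = "quartile_assignment")
}

#' @export
print.quartile_assignment <- function(x, ...) {
  cat(sprintf("<quartile_assignment> n = %d, sizes %s, cuts at %s %%\n",
              nrow(x$assignment), paste(x$sizes, collapse = "/"),
              paste(signif(x$cut_values, 4), collapse = ", ")))
  invisible(x)
}

#' Voxelwise mean SUVR image per quartile group
#'
#' @param suvr_maps list of SUVR `image_volume`s, one per subject, in the
#'   order of the assignment.
#' @param assignment a [assign_quartiles()] result.
#' @return List of four `image_volume`s (quartiles 1--4).
#' @export
mean_suvr_by_quartile <- function(suvr_maps, assignment) {
  stopifnot(inherits(assignment, "quartile_assignment"))
  q <- assignment$assignment$quartile
  if (length(suvr_maps) != length(q))
    stop("mean_suvr_by_quartile: ", length(suvr_maps), " maps for ",
         length(q), " assigned subjects")
  for (i in seq_along(suvr_maps)[-1]) assert_same_grid(suvr_maps[[1]], suvr_maps[[i]])
  lapply(1:4, function(k) {
    ii <- which(q == k)
    if (!length(ii)) stop("mean_suvr_by_quartile: empty quartile ", k)
    acc <- array(0, dim = dim(suvr_maps[[ii[1]]]$data))
    cnt <- array(0, dim = dim(acc))
    for (i in ii) {
      x <- suvr_maps[[i]]$data
      ok <- !is.na(x)
      acc[ok] <- acc[ok] + x[ok]
      cnt <- cnt + ok
    }
    out <- ifelse(cnt > 0, acc / cnt, NA_real_)
    image_volume(out, suvr_maps[[ii[1]]]$voxel_size_mm, suvr_maps[[ii[1]]]$space)
  })
}

#' Regress region-specific positive-voxel extent on quartile group and age
#'
#' Per atlas region, OLS of the subject-level tau-positive extent (voxel
#' count by default, or % positivity) on the numeric quartile group (1--4)
#' and age, optionally plus scanner and scan-duration covariates. The
#' quartile coefficient gets a stratified (within-quartile) BCa bootstrap
#' CI and a Bonferroni-adjusted p over the regions tested. Rows are
#' ordered by unstandardized quartile coefficient, descending.
#'
#' @param extent data.frame with columns `subject_id`, `region`, `extent`
#'   (one row per subject x region).
#' @param assignment a [assign_quartiles()] result covering the subjects.
#' @param subjects data.frame with `subject_id`, `age`, and (if
#'   `extra_covariates`) `scanner`, `scan_duration_min`.
#' @param extra_covariates include scanner and scan-duration regressors
#'   (default `TRUE`).
#' @param n_boot bootstrap replicates for the BCa CI.
#' @param alpha CI level is `1 - alpha`.
#' @param seed RNG seed for the bootstrap.
#' @param min_n regions observed in fewer subjects are skipped with a
#'   warning.
#' @param bonferroni_m Bonferroni family size; defaults to the number of
#'   regions tested in this run.
#' @return data.frame of class `region_extent_table`: one row per region
#'   with `coef_quartile`, `coef_age`, `p_raw`, `p_bonferroni`, `ci_lo`,
#'   `ci_hi`, `n`, sorted by `coef_quartile` descending.
#' @export
region_extent_regression <- function(extent, assignment, subjects,
                                     extra_covariates = TRUE,
                                     n_boot = 2000L, alpha = 0.05, seed,
                                     min_n = 8L, bonferroni_m = NULL) {
  stopifnot(inherits(assignment, "quartile_assignment"))
  if (missing(seed)) stop("region_extent_regression: seed is required")
  asg <- assignment$assignment
  df <- merge(extent, asg[, c("subject_id", "quartile")], by = "subject_id")
  keep_cols <- c("subject_id", "age",
                 if (extra_covariates) c("scanner", "scan_duration_min"))
  df <- merge(df, subjects[, keep_cols], by = "subject_id")
  regions <- unique(extent$region)
  rows <- list()
  for (reg in regions) {
    d <- df[df$region == reg & !is.na(df$extent), , drop = FALSE]
    if (nrow(d) < min_n) {
      warning("region_extent_regression: region '", reg, "' has ", nrow(d),
              " subjects (< ", min_n, "); skipped")
      next
    }
    X <- cbind(1, quartile = d$quartile, age = d$age)
    if (extra_covariates)
      X <- cbind(X, scanner = as.numeric(d$scanner == "HRRT"),
                 duration = d$scan_duration_min)
    y <- d$extent
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    res <- fit$residuals
    n <- nrow(d); p <- ncol(X)
    sigma2 <- sum(res^2) / (n - p)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se_q <- sqrt(sigma2 * XtXinv[2, 2])
    t_q <- if (se_q > 0) cf[2] / se_q else if (cf[2] == 0) 0 else Inf
    p_raw <- if (is.finite(t_q)) 2 * stats::pt(-abs(t_q), n - p) else 0
    stat <- function(dd, idx) {
      Xi <- X[idx, , drop = FALSE]
      f <- tryCatch(stats::lm.fit(Xi, y[idx]), error = function(e) NULL)
      if (is.null(f) || is.na(f$coefficients[2])) NA_real_ else f$coefficients[2]
    }
    ci <- bca_ci(seq_len(n), stat, n_boot = n_boot, alpha = alpha,
                 strata = d$quartile, seed = seed)
    rows[[reg]] <- data.frame(region = reg, coef_quartile = unname(cf[2]),
                              coef_age = unname(cf[3]), p_raw = unname(p_raw),
                              ci_lo = ci[1], ci_hi = ci[2], n = n,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("region_extent_regression: no region had enough subjects")
  out <- do.call(rbind, rows)
  m <- if (is.null(bonferroni_m)) nrow(out) else bonferroni_m
  out$p_bonferroni <- bonferroni(out$p_raw, m)
  out <- out[order(-out$coef_quartile), ]
  rownames(out) <- NULL
  class(out) <- c("region_extent_table", "data.frame")
  out
}
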