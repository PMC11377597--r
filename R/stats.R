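#' Paired t-test on two within-subject measurement vectors
#'
#' Complete-case paired t: incomplete pairs are dropped, the t statistic is
#' `mean(d) / (sd(d) / sqrt(n))` on `d = a - b` (n - 1 denominator SD) with
#' a two-sided p from the t distribution on n - 1 df. Optionally attaches a
#' BCa bootstrap CI for the mean difference.
#'
#' @param a,b numeric vectors of equal length (e.g. mean w in tau-positive
#'   vs tau-negative voxels per subject).
#' @param n_boot if not `NULL`, number of bootstrap replicates for a BCa CI
#'   of `mean(d)`.
#' @param seed RNG seed for the bootstrap (required when `n_boot` is set).
#' @param alpha two-sided CI level is `1 - alpha`.
#' @return Object of class `paired_comparison`: `n_pairs`, `mean_a`,
#'   `mean_b`, `mean_diff`, `sd_a`, `sd_b`, `sd_diff`, `t_stat`,
#'   `p_two_sided`, `degenerate`, `bca_ci_diff`.
#' @export
paired_t <- function(a, b, n_boot = NULL, seed = NULL, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired_t: unequal lengths")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("paired_t: fewer than 3 complete pairs (", n, ")")
  d <- a - b
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  if (degenerate) {
    t_stat <- if (mean(d) == 0) 0 else NA_real_
    p <- if (mean(d) == 0) 1 else NA_real_
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  ci <- NULL
  if (!is.null(n_boot)) {
    if (is.null(seed)) stop("paired_t: bootstrap requires a seed")
    ci <- bca_ci(d, function(x, idx) mean(x[idx]), n_boot = n_boot,
                 alpha = alpha, seed = seed)
  }
  structure(list(n_pairs = n, mean_a = mean(a), mean_b = mean(b),
                 mean_diff = mean(d), sd_a = stats::sd(a), sd_b = stats::sd(b),
                 sd_diff = sd_d, t_stat = t_stat, p_two_sided = p,
                 degenerate = degenerate, bca_ci_diff = ci),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t: n = %d, mean diff = %.4g (%.4g vs %.4g), t = %.3f, p = %.4g\n",
              x$n_pairs, x$mean_diff, x$mean_a, x$mean_b, x$t_stat, x$p_two_sided))
  if (!is.null(x$bca_ci_diff))
    cat(sprintf("  BCa CI of the mean difference: [%.4g, %.4g]\n",
                x$bca_ci_diff[1], x$bca_ci_diff[2]))
  if (x$degenerate) cat("  (degenerate: zero-variance differences)\n")
  invisible(x)
}

#' Partial Pearson correlation controlling for covariates
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals. The two-sided p comes from
#' `t = r * sqrt(df / (1 - r^2))` on `df = n - 2 - k`. With no covariates
#' this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame with `k` columns, or `NULL`.
#' @param n_boot,seed,alpha as in [paired_t()]; the BCa CI resamples
#'   subjects and recomputes the partial correlation.
#' @return Object of class `partial_correlation`: `r`, `n`, `k_covariates`,
#'   `df`, `p_two_sided`, `degenerate`, `bca_ci`.
#' @export
partial_pearson <- function(x, y, covariates = NULL, n_boot = NULL,
                            seed = NULL, alpha = 0.05) {
  if (length(x) != length(y)) stop("partial_pearson: unequal lengths")
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(Z)) keep <- keep & !apply(is.na(Z), 1, any)
  x <- x[keep]; y <- y[keep]; Z <- if (is.null(Z)) NULL else Z[keep, , drop = FALSE]
  n <- length(x); k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 2L) stop("partial_pearson: n = ", n, " too small for k = ", k, " covariates")
  r <- .partial_r(x, y, Z)
  df <- n - 2L - k
  degenerate <- abs(r) >= 1 - 1e-12
  p <- if (degenerate) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  ci <- NULL
  if (!is.null(n_boot)) {
    if (is.null(seed)) stop("partial_pearson: bootstrap requires a seed")
    dat <- seq_len(n)
    ci <- bca_ci(dat, function(ii, idx) {
      j <- ii[idx]
      Zj <- if (is.null(Z)) NULL else Z[j, , drop = FALSE]
      tryCatch(.partial_r(x[j], y[j], Zj), error = function(e) NA_real_)
    }, n_boot = n_boot, alpha = alpha, seed = seed)
  }
  structure(list(r = r, n = n, k_covariates = k, df = df, p_two_sided = p,
                 degenerate = degenerate, bca_ci = ci),
            class = "partial_correlation")
}

.partial_r <- function(x, y, Z) {
  if (is.null(Z)) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    X <- cbind(1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      piv <- qx$pivot[seq_len(qx$rank)]
      bad <- setdiff(seq_len(ncol(X)), piv) - 1L  # covariate column numbers
      stop("partial_pearson: rank-deficient covariates (collinear column ",
           paste(bad, collapse = ", "), ")")
    }
    rx <- stats::resid(stats::lm.fit(X, x))
    ry <- stats::resid(stats::lm.fit(X, y))
    # a variable explained exactly by the covariates leaves numerically zero
    # residuals: its partial correlation with anything is 0, not noise
    if (sum(rx^2) <= 1e-20 * max(sum((x - mean(x))^2), .Machine$double.xmin) ||
        sum(ry^2) <= 1e-20 * max(sum((y - mean(y))^2), .Machine$double.xmin))
      return(0)
  }
  den <- sqrt(sum(rx^2) * sum(ry^2))
  if (den == 0) stop("partial_pearson: zero-variance residuals")
  sum(rx * ry) / den
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("Partial Pearson r = %.3f (n = %d, k = %d covariates), p = %.4g\n",
              x$r, x$n, x$k_covariates, x$p_two_sided))
  if (!is.null(x$bca_ci))
    cat(sprintf("  BCa CI: [%.3f, %.3f]\n", x$bca_ci[1], x$bca_ci[2]))
  invisible(x)
}

#' Bias-corrected accelerated (BCa) bootstrap confidence interval
#'
#' Resamples records with replacement (within strata when given), computes
#' the statistic on each resample, and returns the BCa interval: the
#' bias-correction `z0` is the normal quantile of the proportion of
#' bootstrap statistics below the point estimate, the acceleration `a`
#' comes from the jackknife skewness formula, and the adjusted percentiles
#' are read off the bootstrap distribution. With `z0 = 0` and `a = 0`
#' (forcible via the override arguments) the interval reduces exactly to
#' the percentile interval.
#'
#' Resamples on which the statistic is undefined (`NA`) are redrawn; more
#' than 10% redraws is an error.
#'
#' @param data an indexable vector or data.frame of records.
#' @param stat_fn `function(data, indices)` returning a scalar.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param alpha interval is `1 - alpha`, equal-tailed.
#' @param strata optional vector of stratum labels (resampling is done
#'   within each stratum, preserving stratum sizes).
#' @param seed RNG seed; required, no hidden global randomness.
#' @param z0,accel optional overrides of the bias correction and
#'   acceleration (used by reduction tests; `NULL` = estimate).
#' @return `c(lo, hi)` with attributes `z0`, `accel`, `n_redrawn`,
#'   `t0`.
#' @export
bca_ci <- function(data, stat_fn, n_boot = 2000L, alpha = 0.05, strata = NULL,
                   seed, z0 = NULL, accel = NULL) {
  if (missing(seed) || is.null(seed)) stop("bca_ci: seed is required")
  if (n_boot < 200L) stop("bca_ci: n_boot must be >= 200")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2L) stop("bca_ci: need at least 2 records")
  idx_all <- seq_len(n)
  t0 <- stat_fn(data, idx_all)
  if (!is.finite(t0)) stop("bca_ci: statistic undefined on the full sample")
  set.seed(seed)
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != n) stop("bca_ci: strata length mismatch")
    by_str <- split(idx_all, strata)
  }
  draw <- function() {
    if (is.null(strata)) sample.int(n, n, replace = TRUE)
    else unlist(lapply(by_str, function(ii) ii[sample.int(length(ii), length(ii), replace = TRUE)]),
                use.names = FALSE)
  }
  t_boot <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      tb <- stat_fn(data, draw())
      if (is.finite(tb)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 0.1 * n_boot)
        stop("bca_ci: statistic undefined on more than 10% of resamples")
    }
    t_boot[b] <- tb
  }
  if (all(t_boot == t_boot[1]) && t_boot[1] == t0) {
    out <- c(t0, t0)
    attributes(out) <- list(z0 = 0, accel = 0, n_redrawn = n_redrawn, t0 = t0)
    return(out)
  }
  if (is.null(z0)) {
    prop <- mean(t_boot < t0) + 0.5 * mean(t_boot == t0)
    prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
    z0 <- stats::qnorm(prop)
  }
  if (is.null(accel)) {
    # jackknife over all observations (pooled across strata)
    jk <- vapply(idx_all, function(i) stat_fn(data, idx_all[-i]), numeric(1))
    if (anyNA(jk)) stop("bca_ci: statistic undefined on a jackknife sample")
    u <- mean(jk) - jk
    denom <- sum(u^2)^1.5
    accel <- if (denom < 1e-300) 0 else sum(u^3) / (6 * denom)
  }
  zl <- stats::qnorm(alpha / 2); zu <- stats::qnorm(1 - alpha / 2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
  probs <- c(adj(zl), adj(zu))
  out <- .boot_quantile(t_boot, probs)
  attributes(out) <- list(z0 = z0, accel = accel, n_redrawn = n_redrawn, t0 = t0)
  out
}

# Bootstrap-distribution quantile: interpolate order statistics on the
# normal-quantile scale at rank (B + 1) * p (the canonical BCa endpoint rule).
.boot_quantile <- function(t, probs) {
  B <- length(t)
  ts <- sort(t)
  vapply(probs, function(p) {
    rk <- (B + 1) * p
    if (rk <= 1) return(ts[1])
    if (rk >= B) return(ts[B])
    k <- floor(rk)
    if (rk == k) return(ts[k])
    g <- (stats::qnorm(p) - stats::qnorm(k / (B + 1))) /
      (stats::qnorm((k + 1) / (B + 1)) - stats::qnorm(k / (B + 1)))
    ts[k] + g * (ts[k + 1] - ts[k])
  }, numeric(1))
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)` per element. The family size `m` is always explicit —
#' never inferred from the vector length alone.
#'
#' @param p_values numeric vector of raw p values.
#' @param m family size (>= `length(p_values)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values))
    stop("bonferroni: family size m (", m, ") smaller than the number of tests")
  pmin(1, p_values * m)
}
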