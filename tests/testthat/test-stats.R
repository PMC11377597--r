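test_that("paired t matches closed forms and the t CDF", {
  x <- c(1.2, 0.8, 1.5, 0.9)
  r0 <- paired_t(x, x)
  expect_equal(r0$mean_diff, 0)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_two_sided, 1)
  expect_true(r0$degenerate)

  a <- c(2, 1, 4); b <- c(1, 1, 2)        # d = (1, 0, 2)
  r <- paired_t(a, b)
  expect_equal(r$t_stat, sqrt(3), tolerance = 1e-12)
  expect_equal(r$p_two_sided, 2 * pt(-sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(r$mean_diff, r$mean_a - r$mean_b, tolerance = 1e-12)

  set.seed(80)
  u <- rnorm(25); v <- rnorm(25)
  rs <- paired_t(u, v)
  tt <- t.test(u, v, paired = TRUE)       # independent implementation
  expect_equal(rs$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(rs$p_two_sided, tt$p.value, tolerance = 1e-10)
})

test_that("paired t drops incomplete pairs, flips sign on swap, flags degeneracy", {
  a <- c(1, 2, NA, 4, 5); b <- c(0, NA, 1, 1, 1)
  r <- paired_t(a, b)
  expect_equal(r$n_pairs, 3L)
  r2 <- paired_t(b, a)
  expect_equal(r2$t_stat, -r$t_stat)
  expect_equal(r2$p_two_sided, r$p_two_sided)
  rdeg <- paired_t(c(2, 3, 4), c(1, 2, 3))       # constant nonzero diff
  expect_true(rdeg$degenerate)
  expect_true(is.na(rdeg$t_stat))
  expect_error(paired_t(c(1, NA), c(1, 2)), "3 complete")
})

test_that("partial correlation reduces to Pearson with no covariates", {
  set.seed(81)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc <- partial_pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p_two_sided, ct$p.value, tolerance = 1e-10)
  expect_equal(pc$df, 28L)
})

test_that("perfect residualization gives r = 0 and fixtures match the recursion oracle", {
  set.seed(82)
  z <- rnorm(30); x <- rnorm(30)
  pc <- partial_pearson(x, z + 0, covariates = cbind(z))
  expect_lt(abs(pc$r), 1e-10)

  # 10-row fixture, 2 covariates, against the textbook recursion
  X <- c(1.2, 0.4, -0.7, 2.2, 1.1, -0.3, 0.8, 1.9, -1.4, 0.5)
  Y <- c(0.3, 1.1, -0.2, 1.8, 0.9, 0.1, 0.4, 1.5, -1.0, 0.7)
  Z1 <- c(0.5, -0.1, 0.3, 1.2, 0.8, -0.6, 0.2, 1.0, -0.9, 0.4)
  Z2 <- c(2.0, 1.1, 0.7, 2.5, 1.9, 0.6, 1.3, 2.2, 0.1, 1.4)
  r1 <- function(a, b, c.) (cor(a, b) - cor(a, c.) * cor(b, c.)) /
    sqrt((1 - cor(a, c.)^2) * (1 - cor(b, c.)^2))
  # second-order recursion: partial out Z1, then Z2|Z1
  rxy_1 <- r1(X, Y, Z1); rxz2_1 <- r1(X, Z2, Z1); ryz2_1 <- r1(Y, Z2, Z1)
  oracle <- (rxy_1 - rxz2_1 * ryz2_1) / sqrt((1 - rxz2_1^2) * (1 - ryz2_1^2))
  pc2 <- partial_pearson(as.vector(X), Y, cbind(Z1, Z2))
  expect_equal(pc2$r, oracle, tolerance = 1e-10)
  expect_equal(pc2$df, 6L)
})

test_that("partial correlation is affine-invariant and rejects collinearity", {
  set.seed(83)
  x <- rnorm(40); y <- rnorm(40); Z <- matrix(rnorm(80), 40)
  pc <- partial_pearson(x, y, Z)
  pc2 <- partial_pearson(3 * x - 1, -2 * y + 5,
                         cbind(10 * Z[, 1] + 2, -Z[, 2] / 3))
  expect_equal(abs(pc2$r), abs(pc$r), tolerance = 1e-10)
  expect_equal(pc2$r, -pc$r, tolerance = 1e-10)     # one response negated
  expect_error(partial_pearson(x, y, cbind(Z[, 1], 2 * Z[, 1])), "rank")
})

test_that("BCa intervals: degenerate data, percentile reduction, endpoint containment", {
  ci_deg <- bca_ci(rep(2.5, 12), function(d, i) mean(d[i]), n_boot = 400, seed = 1)
  expect_equal(unclass(ci_deg)[1:2], c(2.5, 2.5))

  set.seed(84)
  x <- rnorm(40)
  stat <- function(d, i) mean(d[i])
  forced <- bca_ci(x, stat, n_boot = 999, seed = 5, z0 = 0, accel = 0)
  # rebuild the same bootstrap distribution; with B = 999 the 2.5% / 97.5%
  # percentile endpoints are the 25th and 975th order statistics exactly
  set.seed(5)
  tb <- replicate(999, mean(x[sample.int(40, 40, replace = TRUE)]))
  perc <- sort(tb)[c(25, 975)]
  expect_equal(unclass(forced)[1:2], perc, tolerance = 1e-12)

  full <- bca_ci(x, stat, n_boot = 999, seed = 5)
  expect_gte(full[1], min(tb)); expect_lte(full[2], max(tb))
  expect_lt(full[1], full[2])
})

test_that("BCa is deterministic under seed and narrows as alpha grows", {
  set.seed(85)
  x <- rexp(35)
  stat <- function(d, i) mean(d[i])
  a1 <- bca_ci(x, stat, n_boot = 500, seed = 9)
  a2 <- bca_ci(x, stat, n_boot = 500, seed = 9)
  expect_identical(unclass(a1), unclass(a2))
  w05 <- diff(unclass(bca_ci(x, stat, n_boot = 2000, seed = 9, alpha = 0.05))[1:2])
  w20 <- diff(unclass(bca_ci(x, stat, n_boot = 2000, seed = 9, alpha = 0.20))[1:2])
  expect_lt(w20, w05)
})

test_that("stratified resampling preserves stratum sizes", {
  strata <- rep(1:4, times = c(5, 5, 5, 4))
  set.seed(10)
  x <- rnorm(19) + strata
  sizes_seen <- list()
  ci <- bca_ci(seq_along(x), function(d, i) {
    idx <- d[i]
    if (length(idx) == length(d))           # bootstrap draws, not jackknife
      sizes_seen[[length(sizes_seen) + 1]] <<- as.integer(table(factor(strata[idx], 1:4)))
    mean(x[idx])
  }, n_boot = 200, seed = 11, strata = strata)
  expect_gt(length(sizes_seen), 100)
  for (s in sizes_seen) expect_equal(s, c(5L, 5L, 5L, 4L))
  expect_true(is.numeric(ci))
})

test_that("BCa agrees with the reference bootstrap implementation on one fixture", {
  skip_if_not_installed("boot")
  set.seed(86)
  x <- rgamma(40, shape = 2)
  stat <- function(d, i) mean(d[i])
  mine <- bca_ci(x, stat, n_boot = 4000, seed = 13)
  b <- boot::boot(x, stat, R = 4000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  # same method, independent resampling streams: agree to Monte-Carlo error
  expect_equal(unclass(mine)[1:2], ref, tolerance = 0.03)
})

test_that("undefined statistics are redrawn up to the 10% budget", {
  set.seed(87)
  x <- rnorm(20)
  flaky <- local({
    k <- 0
    function(d, i) { k <<- k + 1; if (k %% 50 == 0) NA_real_ else mean(d[i]) }
  })
  ci <- bca_ci(x, flaky, n_boot = 300, seed = 15)
  expect_gt(attr(ci, "n_redrawn"), 0)
  always_na <- function(d, i) if (length(unique(i)) < 20) NA_real_ else mean(d[i])
  expect_error(bca_ci(x, always_na, n_boot = 300, seed = 15), "10%")
})

test_that("Bonferroni adjustment follows the explicit-family formula", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  set.seed(88)
  p <- runif(7)
  adj <- bonferroni(p, m = 10)
  for (i in seq_along(p)) expect_equal(adj[i], min(1, p[i] * 10))
  expect_error(bonferroni(runif(5), m = 3), "family size")
})

test_that("partial correlation rejects at the nominal rate under an independent null", {
  set.seed(89)
  rej <- replicate(400, {
    x <- rnorm(40); y <- rnorm(40); Z <- matrix(rnorm(80), 40)
    partial_pearson(x, y, Z)$p_two_sided < 0.05
  })
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.08)
})
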