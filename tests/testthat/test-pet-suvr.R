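const_vol <- function(value, dims = c(6, 6, 6)) {
  image_volume(array(value, dim = dims))
}

test_that("frame averaging weights frames by overlap with the window", {
  f1 <- list(vol = const_vol(1), start = 80, end = 100)
  expect_equal(average_frames(list(f1), c(80, 100))$data, const_vol(1)$data)
  f2a <- list(vol = const_vol(1), start = 80, end = 90)
  f2b <- list(vol = const_vol(3), start = 90, end = 100)
  expect_equal(average_frames(list(f2a, f2b), c(80, 100))$data[1], 2.0)
  f3b <- list(vol = const_vol(4), start = 90, end = 100)
  # (10*1 + 5*4) / 15 = 2
  expect_equal(average_frames(list(f2a, f3b), c(80, 95))$data[1], 2.0)
  # unweighted flag averages intersecting frames equally
  expect_equal(average_frames(list(f2a, f3b), c(80, 95), weighted = FALSE)$data[1], 2.5)
})

test_that("frame averaging refuses uncovered windows and unsorted frames", {
  f1 <- list(vol = const_vol(1), start = 80, end = 88)
  f2 <- list(vol = const_vol(2), start = 92, end = 100)
  expect_error(average_frames(list(f1, f2), c(80, 100)), "gap at \\[88, 92\\]")
  expect_error(average_frames(list(f1), c(80, 100)), "gap")
  f3 <- list(vol = const_vol(1), start = 85, end = 95)
  expect_error(average_frames(list(f3, f1), c(80, 100)), "sorted")
})

test_that("SUVR equals elementwise division by the reference mean (brute-force oracle)", {
  expect_equal(compute_suvr(const_vol(3), array(TRUE, c(6, 6, 6)))$data[1], 1.0)
  act <- rand_volume(c(8, 8, 8), seed = 21)
  set.seed(22)
  ref <- array(runif(512) > 0.7, c(8, 8, 8))
  out <- compute_suvr(act, ref)
  # independent loop oracle
  tot <- 0; cnt <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    if (ref[i, j, k]) { tot <- tot + act$data[i, j, k]; cnt <- cnt + 1 }
  expect_equal(out$data, act$data / (tot / cnt), tolerance = 1e-12)
  expect_error(compute_suvr(act, array(FALSE, c(8, 8, 8))), "empty reference")
  neg <- image_volume(-act$data)
  expect_error(compute_suvr(neg, ref), "<= 0")
})

test_that("Gaussian smoothing preserves constants and matches a dense-convolution oracle", {
  cv <- const_vol(2.5, c(10, 10, 10))
  sm <- smooth_volume(cv, c(6, 6, 6))
  expect_equal(sm$data, cv$data, tolerance = 1e-10)

  # impulse along one axis vs direct dense convolution, sigma = 1 voxel
  n <- 31
  imp <- image_volume(array(0, c(n, 1, 1)), voxel_size_mm = c(1, 1, 1))
  imp$data[16, 1, 1] <- 1
  fwhm <- sqrt(8 * log(2))      # sigma = 1 voxel
  sm1 <- smooth_volume(imp, c(fwhm, 0, 0))
  h <- ceiling(3.5)
  w <- dnorm(seq(-h, h)); w <- w / sum(w)
  dense <- stats::convolve(imp$data[, 1, 1], rev(w), type = "open")
  dense <- dense[(h + 1):(h + n)]
  expect_equal(sm1$data[, 1, 1], dense, tolerance = 1e-10)
})

test_that("interior point-source mass is conserved under zero-padding smoothing", {
  v <- image_volume(array(0, c(24, 24, 24)))
  v$data[12, 12, 12] <- 7
  sm <- smooth_volume(v, c(4, 4, 4), boundary = "zero")
  expect_equal(sum(sm$data), 7, tolerance = 1e-6)
})

test_that("masked smoothing never mixes values across the mask and fills NA outside", {
  v <- rand_volume(c(8, 8, 8), seed = 30)
  mask <- array(FALSE, c(8, 8, 8)); mask[3:6, 3:6, 3:6] <- TRUE
  v$data[1, 1, 1] <- 1e6            # would leak if the mask were ignored
  sm <- smooth_volume(v, c(5, 5, 5), mask = mask)
  expect_true(all(is.na(sm$data[!mask])))
  expect_true(all(sm$data[mask] < 100))
  # constant inside mask stays constant (renormalized support)
  v2 <- const_vol(1.7, c(8, 8, 8))
  sm2 <- smooth_volume(v2, c(5, 5, 5), mask = mask)
  expect_equal(sm2$data[mask], rep(1.7, sum(mask)), tolerance = 1e-10)
})

test_that("positivity thresholding partitions GM and honours the comparator", {
  gm <- array(TRUE, c(4, 4, 4))
  low <- const_vol(1.0, c(4, 4, 4))
  r <- threshold_positivity(low, gm)
  expect_equal(sum(r$positive_mask), 0)
  expect_equal(sum(r$negative_mask), 64)
  at <- const_vol(1.30, c(4, 4, 4))
  expect_equal(sum(threshold_positivity(at, gm, cmp = ">=")$positive_mask), 64)
  expect_equal(sum(threshold_positivity(at, gm, cmp = ">")$positive_mask), 0)
  expect_error(threshold_positivity(low, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("random-volume positivity masks match exhaustive per-voxel comparison", {
  for (s in 1:10) {
    suvr <- rand_volume(c(4, 4, 4), seed = 100 + s, lo = 0.8, hi = 1.8)
    set.seed(200 + s)
    gm <- array(runif(64) > 0.3, c(4, 4, 4))
    if (!any(gm)) next
    r <- threshold_positivity(suvr, gm, threshold = 1.30)
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_identical(r$positive_mask[i, j, k],
                       gm[i, j, k] && suvr$data[i, j, k] >= 1.30)
      expect_identical(r$negative_mask[i, j, k],
                       gm[i, j, k] && suvr$data[i, j, k] < 1.30)
    }
  }
})

test_that("percent positivity matches hand counts globally and per region", {
  d <- c(3, 3, 3)
  suvr <- image_volume(array(1, d))
  suvr$data[1:7] <- 2                      # 7 positive of 27
  r <- threshold_positivity(suvr, array(TRUE, d))
  expect_equal(percent_positivity(r)$global, 100 * 7 / 27)
  all_pos <- threshold_positivity(image_volume(array(2, d)), array(TRUE, d))
  expect_equal(percent_positivity(all_pos)$global, 100)
  none <- threshold_positivity(image_volume(array(1, d)), array(TRUE, d))
  expect_equal(percent_positivity(none)$global, 0)
  # per-region vs loop oracle
  lab <- array(1L, d); lab[14:27] <- 2L
  at <- label_atlas(lab, c(`1` = "front", `2` = "back"))
  pp <- percent_positivity(r, at)
  expect_equal(unname(pp$by_region["front"]), 100 * sum(suvr$data[1:13] == 2) / 13)
  expect_equal(unname(pp$by_region["back"]), 100 * sum(suvr$data[14:27] == 2) / 14)
})

test_that("percent positivity is monotone non-increasing in the threshold", {
  suvr <- rand_volume(c(6, 6, 6), seed = 33, lo = 0.8, hi = 2)
  gm <- array(TRUE, c(6, 6, 6))
  thr <- seq(0.9, 1.9, by = 0.1)
  pct <- vapply(thr, function(t)
    percent_positivity(threshold_positivity(suvr, gm, threshold = t))$global,
    numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("smoothing before thresholding is not the same as thresholding first", {
  cfg <- tiny_cfg(seed = 44)
  ath <- generate_athletes(cfg, n = 1L)
  gm <- sim_gm_mask(cfg)
  k <- smoothing_kernel("PETCT")
  smooth_first <- threshold_positivity(
    smooth_volume(ath$suvr[[1]], k, mask = gm), gm)
  thr_first_mask <- threshold_positivity(ath$suvr[[1]], gm)$positive_mask
  smoothed_mask <- smooth_volume(image_volume(thr_first_mask + 0), k, mask = gm)
  thr_then_smooth <- as_mask(smoothed_mask)
  expect_false(identical(smooth_first$positive_mask, thr_then_smooth))
})

test_that("scanner kernels carry the published anisotropic FWHM values", {
  expect_equal(smoothing_kernel("PETCT"), c(6.55, 6.55, 7.75))
  expect_equal(smoothing_kernel("HRRT"), c(7.37, 7.37, 7.91))
})
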