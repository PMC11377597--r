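make_linear_controls <- function(n = 20, dims = c(5, 5, 5), sigma = 0,
                                 seed = 50, b0 = 0.5, ba = -0.002, bt = 1e-4) {
  set.seed(seed)
  age <- runif(n, 30, 70); tiv <- rnorm(n, 1500, 100)
  gm <- lapply(seq_len(n), function(i) {
    vals <- array(b0 + ba * age[i] + bt * tiv[i], dim = dims)
    if (sigma > 0) vals <- vals + array(rnorm(prod(dims), 0, sigma), dim = dims)
    image_volume(vals)
  })
  list(gm = gm, subjects = data.frame(subject_id = sprintf("c%02d", 1:n),
                                      age = age, tiv = tiv),
       truth = c(b0 = b0, ba = ba, bt = bt))
}

test_that("noiseless linear data is interpolated exactly", {
  ctl <- make_linear_controls(sigma = 0)
  m <- fit_normative(ctl$gm, ctl$subjects)
  co <- coef(m)
  expect_equal(unname(co["intercept", 1]), unname(ctl$truth["b0"]), tolerance = 1e-8)
  expect_equal(unname(co["age", 1]), unname(ctl$truth["ba"]), tolerance = 1e-8)
  expect_equal(unname(co["tiv", 1]), unname(ctl$truth["bt"]), tolerance = 1e-8)
  expect_lt(max(m$resid_sd), 1e-10)
})

test_that("single-voxel fit equals the closed-form normal-equations solution", {
  ctl <- make_linear_controls(sigma = 0.05, seed = 51)
  m <- fit_normative(ctl$gm, ctl$subjects)
  v <- 7                                    # arbitrary voxel
  y <- vapply(ctl$gm, function(g) g$data[v], numeric(1))
  X <- cbind(1, ctl$subjects$age, ctl$subjects$tiv)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)   # independent 3x3 solve
  co <- coef(m)[, v]
  expect_equal(unname(co), as.vector(beta_oracle), tolerance = 1e-8)
  res <- y - X %*% beta_oracle
  expect_equal(m$resid_sd[v], sqrt(sum(res^2) / (length(y) - 3)), tolerance = 1e-10)
})

test_that("covariate-independent data yields null slopes within 3 SE", {
  set.seed(52)
  n <- 60
  age <- runif(n, 30, 70); tiv <- rnorm(n, 1500, 100)
  gm <- lapply(1:n, function(i) image_volume(array(rnorm(27, 0.5, 0.05), c(3, 3, 3))))
  m <- fit_normative(gm, data.frame(age = age, tiv = tiv))
  co <- coef(m)
  # SE of the slope from the classical formula
  se_age <- m$resid_sd / (sd(age) * sqrt(n - 1))
  expect_true(all(abs(co["age", ]) < 3.5 * se_age))
})

test_that("degenerate designs and undersized cohorts are rejected", {
  ctl <- make_linear_controls()
  expect_error(fit_normative(ctl$gm[1:5], ctl$subjects[1:5, ]), "at least 10")
  s2 <- ctl$subjects; s2$age <- 50
  expect_error(fit_normative(ctl$gm, s2), "age")
  s3 <- ctl$subjects; s3$subject_id[2] <- s3$subject_id[1]
  expect_error(fit_normative(ctl$gm, s3), "duplicate")
})

test_that("w-score maps are zero at the prediction and one at +1 residual SD", {
  ctl <- make_linear_controls(sigma = 0.05, seed = 53)
  m <- fit_normative(ctl$gm, ctl$subjects)
  pred <- predict(m, age = 50, tiv = 1500)
  w0 <- wscore_map(m, pred, age = 50, tiv = 1500)
  expect_equal(max(abs(w0$data)), 0, tolerance = 1e-10)
  shifted <- image_volume(pred$data + array(m$resid_sd, dim = dim(pred$data)))
  w1 <- wscore_map(m, shifted, age = 50, tiv = 1500)
  expect_equal(range(w1$data), c(1, 1), tolerance = 1e-10)
})

test_that("a random voxel's w-score equals the hand formula from exported grids", {
  cfg <- tiny_cfg(seed = 54, n_controls = 30L)
  ctl <- generate_controls(cfg)
  m <- fit_normative(ctl$gm, ctl$subjects, fit_mask = sim_gm_mask(cfg))
  ath <- generate_athletes(cfg, n = 1L)
  w <- suppressWarnings(wscore_map(m, ath$gm[[1]], ath$subjects$age[1],
                                   ath$subjects$tiv[1]))
  co <- coef(m)
  set.seed(55)
  for (pick in sample(length(m$vox), 5)) {
    v <- m$vox[pick]
    pred <- unname(co["intercept", pick] + co["age", pick] * ath$subjects$age[1] +
                     co["tiv", pick] * ath$subjects$tiv[1])
    expect_equal(w$data[v], (ath$gm[[1]]$data[v] - pred) / m$resid_sd[pick],
                 tolerance = 1e-8)
  }
})

test_that("w-scores are invariant to affine rescaling of the covariates", {
  ctl <- make_linear_controls(sigma = 0.05, seed = 56)
  m1 <- fit_normative(ctl$gm, ctl$subjects)
  s2 <- ctl$subjects
  s2$age <- s2$age * 12 + 7          # months, offset
  s2$tiv <- s2$tiv / 1000            # litres
  m2 <- fit_normative(ctl$gm, s2)
  obs <- image_volume(ctl$gm[[1]]$data + 0.03)
  w1 <- wscore_map(m1, obs, ctl$subjects$age[1], ctl$subjects$tiv[1])
  w2 <- wscore_map(m2, obs, s2$age[1], s2$tiv[1])
  expect_equal(w1$data, w2$data, tolerance = 1e-8)
})

test_that("w increases strictly with observed GM at a fixed model", {
  ctl <- make_linear_controls(sigma = 0.05, seed = 57)
  m <- fit_normative(ctl$gm, ctl$subjects)
  base <- predict(m, age = 45, tiv = 1450)
  w_lo <- wscore_map(m, base, 45, 1450)
  for (delta in c(0.001, 0.01, 0.1)) {
    w_hi <- wscore_map(m, image_volume(base$data + delta), 45, 1450)
    expect_true(all(w_hi$data > w_lo$data))
  }
})

test_that("extrapolated covariates warn rather than score silently", {
  ctl <- make_linear_controls(sigma = 0.05, seed = 58)
  m <- fit_normative(ctl$gm, ctl$subjects)
  obs <- ctl$gm[[1]]
  expect_warning(wscore_map(m, obs, age = 95, tiv = 1500), "extrapolation")
  expect_warning(wscore_map(m, obs, age = 50, tiv = 3000), "extrapolation")
})

test_that("voxels under the residual-SD floor are set missing", {
  ctl <- make_linear_controls(sigma = 0)          # resid_sd ~ 0 everywhere
  m <- fit_normative(ctl$gm, ctl$subjects)
  w <- wscore_map(m, ctl$gm[[1]], ctl$subjects$age[1], ctl$subjects$tiv[1])
  expect_true(all(is.na(w$data)))
})

test_that("mask means match a brute-force voxel loop and degenerate cases behave", {
  w <- rand_volume(c(5, 5, 5), seed = 59, lo = -2, hi = 2)
  set.seed(60)
  pos <- array(runif(125) > 0.7, c(5, 5, 5))
  neg <- !pos & array(runif(125) > 0.2, c(5, 5, 5))
  s <- extract_mask_means(w, pos, neg)
  tp <- tn <- 0; np <- nn <- 0L
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    if (pos[i, j, k]) { tp <- tp + w$data[i, j, k]; np <- np + 1L }
    if (neg[i, j, k]) { tn <- tn + w$data[i, j, k]; nn <- nn + 1L }
  }
  expect_equal(s$mean_w_pos, tp / np, tolerance = 1e-12)
  expect_equal(s$mean_w_neg, tn / nn, tolerance = 1e-12)
  expect_equal(s$n_vox_pos, np); expect_equal(s$n_vox_neg, nn)

  cw <- image_volume(array(3.3, c(4, 4, 4)))
  half <- array(FALSE, c(4, 4, 4)); half[1:32] <- TRUE
  s2 <- extract_mask_means(cw, half, !half)
  expect_equal(s2$mean_w_pos, 3.3); expect_equal(s2$mean_w_neg, 3.3)

  s3 <- extract_mask_means(cw, array(FALSE, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  expect_true(is.na(s3$mean_w_pos))
  expect_equal(s3$mean_w_neg, 3.3)

  expect_error(extract_mask_means(cw, half, half), "overlap")
})
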