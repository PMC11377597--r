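#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every structural and noise parameter of the synthetic study:
#' grid geometry, cohort sizes, the linear age/TIV effects on grey matter,
#' the tau hotspot field, the tau--atrophy coupling, and the memory--tau
#' coupling. Defaults reproduce the study conditions the pipeline is
#' validated under: 54 controls (ages 26--71), 47 athletes, a 16^3 grid at
#' 2 mm, scanner mix 66% PET/CT vs 34% HRRT and 79% 80--100 min scan
#' windows, and couplings sized so the athlete w-score contrast lands near
#' -0.37 (tau-positive) vs -0.31 (tau-negative) grey matter.
#'
#' @param grid_dims integer triple, >= 8 per axis.
#' @param voxel_size_mm voxel sizes in mm.
#' @param n_controls,n_athletes cohort sizes.
#' @param age_range_controls,age_range_athletes uniform age ranges (years).
#'   Athletes default to the control range so the normative model is never
#'   extrapolated.
#' @param tiv_mean,tiv_sd total intracranial volume distribution (mL).
#' @param education_mean,education_sd education (years), athletes only.
#' @param beta_age grey-matter change per year of age (GM units/year, < 0).
#' @param beta_tiv grey-matter change per mL of TIV (GM units/mL).
#' @param sigma_gm voxelwise residual SD of grey matter (GM units).
#' @param tau_baseline SUVR far from hotspots (about 1.0).
#' @param tau_hotspots list of hotspots, each `list(center=, radius=, peak=)`
#'   with `center` in voxel coordinates, `radius` in voxels and `peak` the
#'   SUVR excess at the centre (before per-subject severity scaling).
#' @param tau_noise_sd voxelwise SUVR measurement noise SD.
#' @param tau_severity_range per-subject uniform multiplier on the hotspot
#'   amplitude; this is what makes % positivity vary across athletes.
#' @param coupling_beta grey-matter loss per unit of tau SUVR excess
#'   (GM units per SUVR; <= 0 couples atrophy to tau).
#' @param atrophy_offset global athlete grey-matter deficit (GM units),
#'   applied everywhere; places the athlete mean w-score below zero.
#' @param atrophy_offset_sd between-subject SD of the global deficit
#'   (GM units); models cohort heterogeneity in overall atrophy. It shifts
#'   a subject's tau-positive and tau-negative w means equally, so it
#'   widens the cohort SD of each mean without touching their difference.
#' @param memory_slope memory composite z per % positivity (<= 0).
#' @param memory_sigma residual SD of the memory composite.
#' @param scanner_p_petct probability an athlete is scanned on PET/CT.
#' @param window_p_80100 probability of the 80--100 min scan window.
#' @param seed integer RNG seed; mandatory, every generator derives its
#'   stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(16L, 16L, 16L),
                       voxel_size_mm = c(2, 2, 2),
                       n_controls = 54L,
                       n_athletes = 47L,
                       age_range_controls = c(26, 71),
                       age_range_athletes = c(26, 71),
                       tiv_mean = 1500, tiv_sd = 120,
                       education_mean = 15, education_sd = 2,
                       beta_age = -0.002,
                       beta_tiv = 2e-4,
                       sigma_gm = 0.05,
                       tau_baseline = 1.0,
                       tau_hotspots = NULL,
                       tau_noise_sd = 0.05,
                       tau_severity_range = c(0.8, 1.8),
                       coupling_beta = -0.005,
                       atrophy_offset = -0.015,
                       atrophy_offset_sd = 0.02,
                       memory_slope = -0.03,
                       memory_sigma = 0.5,
                       scanner_p_petct = 0.66,
                       window_p_80100 = 0.787,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 8L))
    stop("sim_config: grid dims must be a triple with every axis >= 8")
  if (sigma_gm < 0 || tau_noise_sd < 0 || memory_sigma < 0 || tiv_sd < 0 ||
      atrophy_offset_sd < 0)
    stop("sim_config: SDs must be >= 0")
  if (is.null(tau_hotspots)) tau_hotspots <- .default_hotspots(grid_dims)
  for (h in tau_hotspots) {
    if (any(h$center < 1) || any(h$center > grid_dims))
      stop("sim_config: hotspot center ", paste(h$center, collapse = ","),
           " outside grid ", paste(grid_dims, collapse = "x"))
    if (h$radius <= 0 || h$peak < 0) stop("sim_config: hotspot radius/peak invalid")
  }
  cfg <- list(grid_dims = grid_dims, voxel_size_mm = as.numeric(voxel_size_mm),
              n_controls = as.integer(n_controls), n_athletes = as.integer(n_athletes),
              age_range_controls = age_range_controls,
              age_range_athletes = age_range_athletes,
              tiv_mean = tiv_mean, tiv_sd = tiv_sd,
              education_mean = education_mean, education_sd = education_sd,
              beta_age = beta_age, beta_tiv = beta_tiv, sigma_gm = sigma_gm,
              tau_baseline = tau_baseline, tau_hotspots = tau_hotspots,
              tau_noise_sd = tau_noise_sd, tau_severity_range = tau_severity_range,
              coupling_beta = coupling_beta, atrophy_offset = atrophy_offset,
              atrophy_offset_sd = atrophy_offset_sd,
              memory_slope = memory_slope, memory_sigma = memory_sigma,
              scanner_p_petct = scanner_p_petct, window_p_80100 = window_p_80100,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Anterior/lateral hotspot placement (frontotemporal-weighted), in voxel
# coordinates scaled to the grid. Pattern realism is cosmetic; the coupling
# structure is what the tests exercise.
.default_hotspots <- function(gd) {
  frac <- function(f) 1 + f * (gd - 1)
  r <- 0.29 * min(gd)
  list(
    list(center = frac(c(0.30, 0.72, 0.55)), radius = r, peak = 1.15),
    list(center = frac(c(0.70, 0.72, 0.55)), radius = r, peak = 1.15),
    list(center = frac(c(0.28, 0.40, 0.45)), radius = 0.8 * r, peak = 0.90),
    list(center = frac(c(0.72, 0.40, 0.45)), radius = 0.8 * r, peak = 0.90)
  )
}

# Fixed smooth baseline grey-matter template: sum of low-frequency
# cosines/sines of voxel coordinates. Not a brain template; no download
# is ever required. GM units are probability-like (0..~0.75).
.gm_template <- function(cfg) {
  gd <- cfg$grid_dims
  xf <- (seq_len(gd[1]) - 0.5) / gd[1]
  yf <- (seq_len(gd[2]) - 0.5) / gd[2]
  zf <- (seq_len(gd[3]) - 0.5) / gd[3]
  sx <- sin(pi * xf); sy <- sin(pi * yf); sz <- sin(pi * zf)
  main <- outer(outer(sx, sy), sz)              # central bump
  ripple <- outer(outer(cos(2 * pi * xf), cos(2 * pi * yf)), rep(1, gd[3]))
  0.22 + 0.48 * main + 0.03 * ripple
}

#' Grey-matter analysis mask of the synthetic space
#'
#' Voxels where the baseline template exceeds 0.35 GM units (the interior
#' of the synthetic "brain").
#'
#' @param cfg a [sim_config()].
#' @return Logical 3-D array.
#' @export
sim_gm_mask <- function(cfg) .gm_template(cfg) > 0.35

# Unit-severity tau excess field: sum of compact radial-cosine bumps.
.hotspot_field <- function(cfg) {
  gd <- cfg$grid_dims
  out <- array(0, dim = gd)
  cx <- slice.index(out, 1); cy <- slice.index(out, 2); cz <- slice.index(out, 3)
  for (h in cfg$tau_hotspots) {
    r <- sqrt((cx - h$center[1])^2 + (cy - h$center[2])^2 + (cz - h$center[3])^2)
    b <- ifelse(r <= h$radius, h$peak * cos(pi / 2 * r / h$radius)^2, 0)
    out <- out + b
  }
  out
}

.sub_seed <- function(cfg, k) (cfg$seed %% 1000000L) * 1000L + k

#' Generate the healthy-control cohort
#'
#' Ages uniform on the configured control range, TIV normal; each
#' grey-matter map is the smooth baseline template plus linear age and TIV
#' effects plus voxelwise Gaussian noise. Deterministic given the config
#' seed.
#'
#' @param cfg a [sim_config()].
#' @param n number of controls (defaults to `cfg$n_controls`).
#' @param stream integer offset selecting an independent RNG stream, so
#'   independent control samples (e.g. fit vs held-out) can be drawn from
#'   one config.
#' @return `list(subjects = data.frame, gm = list of image_volume)`.
#' @export
generate_controls <- function(cfg, n = cfg$n_controls, stream = 0L) {
  set.seed(.sub_seed(cfg, 1L + 10L * stream))
  tpl <- .gm_template(cfg)
  age <- stats::runif(n, cfg$age_range_controls[1], cfg$age_range_controls[2])
  tiv <- stats::rnorm(n, cfg$tiv_mean, cfg$tiv_sd)
  subjects <- data.frame(
    subject_id = sprintf("ctl%02d_%03d", stream, seq_len(n)),
    group = "control", age = age, tiv = tiv,
    stringsAsFactors = FALSE)
  gm <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- tpl + cfg$beta_age * age[i] + cfg$beta_tiv * tiv[i]
    if (cfg$sigma_gm > 0)
      vals <- vals + array(stats::rnorm(length(tpl), 0, cfg$sigma_gm), dim = dim(tpl))
    gm[[i]] <- image_volume(vals, cfg$voxel_size_mm)
  }
  list(subjects = subjects, gm = gm)
}

#' Generate the athlete cohort
#'
#' Each athlete's SUVR map is `tau_baseline` plus a per-subject severity
#' multiple of the hotspot field plus voxelwise noise. The grey-matter map
#' is the control-model prediction for the athlete's age/TIV, plus the
#' global `atrophy_offset`, plus `coupling_beta` times the noise-free tau
#' excess (atrophy tracks the structural tau burden, not PET measurement
#' noise), plus voxelwise noise. Scanner and scan-window labels are
#' assigned at the configured proportions.
#'
#' @param cfg a [sim_config()].
#' @param n number of athletes.
#' @return `list(subjects, gm, suvr, truth)`; `truth` carries per-subject
#'   severity and the unit hotspot field.
#' @export
generate_athletes <- function(cfg, n = cfg$n_athletes) {
  set.seed(.sub_seed(cfg, 2L))
  tpl <- .gm_template(cfg)
  hot <- .hotspot_field(cfg)
  age <- stats::runif(n, cfg$age_range_athletes[1], cfg$age_range_athletes[2])
  tiv <- stats::rnorm(n, cfg$tiv_mean, cfg$tiv_sd)
  edu <- round(stats::rnorm(n, cfg$education_mean, cfg$education_sd))
  sev <- stats::runif(n, cfg$tau_severity_range[1], cfg$tau_severity_range[2])
  offset <- cfg$atrophy_offset + stats::rnorm(n, 0, cfg$atrophy_offset_sd)
  scanner <- ifelse(stats::runif(n) < cfg$scanner_p_petct, "PETCT", "HRRT")
  window <- ifelse(stats::runif(n) < cfg$window_p_80100, "W80_100", "W80_90")
  subjects <- data.frame(
    subject_id = sprintf("ath_%03d", seq_len(n)),
    group = "athlete", age = age, tiv = tiv, education = edu,
    scanner = scanner, scan_window = window,
    scan_duration_min = ifelse(window == "W80_100", 20, 10),
    tau_severity = sev, stringsAsFactors = FALSE)
  gm <- suvr <- vector("list", n)
  nv <- length(tpl)
  for (i in seq_len(n)) {
    excess <- sev[i] * hot                       # noise-free tau burden
    sv <- cfg$tau_baseline + excess
    if (cfg$tau_noise_sd > 0)
      sv <- sv + array(stats::rnorm(nv, 0, cfg$tau_noise_sd), dim = dim(tpl))
    suvr[[i]] <- image_volume(sv, cfg$voxel_size_mm)
    gv <- tpl + cfg$beta_age * age[i] + cfg$beta_tiv * tiv[i] +
      offset[i] + cfg$coupling_beta * pmax(excess, 0)
    if (cfg$sigma_gm > 0)
      gv <- gv + array(stats::rnorm(nv, 0, cfg$sigma_gm), dim = dim(tpl))
    gm[[i]] <- image_volume(gv, cfg$voxel_size_mm)
  }
  list(subjects = subjects, gm = gm, suvr = suvr,
       truth = list(severity = sev, hotspot_field = hot,
                    coupling_beta = cfg$coupling_beta,
                    atrophy_offset = cfg$atrophy_offset))
}

#' Generate neuropsychological test scores with a tau-coupled memory domain
#'
#' Memory-test z-scores are drawn so the subject's memory composite equals
#' `memory_slope * pct_positivity + N(0, memory_sigma)` exactly (the
#' within-battery jitter is centred per subject). The speed and executive
#' batteries are drawn independently of tau, mirroring null domains.
#'
#' @param subjects athlete subject data.frame.
#' @param pct_positivity per-subject global % positivity (same order).
#' @param cfg a [sim_config()].
#' @return data.frame of test-level scores (z and t scales) per subject.
#' @export
generate_neuropsych <- function(subjects, pct_positivity, cfg) {
  n <- nrow(subjects)
  if (length(pct_positivity) != n)
    stop("generate_neuropsych: need one % positivity per subject (",
         n, " subjects, ", length(pct_positivity), " values)")
  set.seed(.sub_seed(cfg, 3L))
  target <- cfg$memory_slope * pct_positivity +
    stats::rnorm(n, 0, cfg$memory_sigma)
  centered_jitter <- function(n_tests, sd = 0.3) {
    e <- stats::rnorm(n_tests, 0, sd); e - mean(e)
  }
  mem <- t(vapply(seq_len(n), function(i) target[i] + centered_jitter(3),
                  numeric(3)))
  speed <- matrix(stats::rnorm(n * 6), n, 6)
  exec_t <- matrix(stats::rnorm(n * 6, 50, 10), n, 6)
  out <- data.frame(subject_id = subjects$subject_id,
                    ravlt_trials_z = mem[, 1], ravlt_delay_z = mem[, 2],
                    rvdlt_trials_z = mem[, 3],
                    tmt_a_z = speed[, 1], digit_fwd_z = speed[, 2],
                    stroop_color_z = speed[, 3], stroop_word_z = speed[, 4],
                    sdmt_written_z = speed[, 5], sdmt_oral_z = speed[, 6],
                    digit_bwd_t = exec_t[, 1], wcst_err_t = exec_t[, 2],
                    wcst_persev_err_t = exec_t[, 3],
                    wcst_nonpersev_err_t = exec_t[, 4],
                    wcst_conceptual_t = exec_t[, 5], tmt_b_t = exec_t[, 6],
                    stringsAsFactors = FALSE)
  attr(out, "true_memory_composite") <- target
  out
}

#' Generate plasma/CSF biofluid panels straddling the gating thresholds
#'
#' Each subject is assigned one assay route (in-house plasma, commercial V2
#' plasma, or the CSF triplet). Subjects drawn positive receive values
#' above the applicable threshold by a uniform relative margin; negatives
#' fall below it. The returned `true_positive` column is the generator's
#' own label, against which the gate is validated.
#'
#' @param subjects subject data.frame with `age`.
#' @param fraction_positive proportion of AD-biomarker-positive subjects.
#' @param cfg a [sim_config()].
#' @return data.frame of panel values plus `true_positive`.
#' @export
generate_biofluids <- function(subjects, fraction_positive, cfg) {
  if (fraction_positive < 0 || fraction_positive > 1)
    stop("generate_biofluids: fraction_positive must be in [0, 1]")
  n <- nrow(subjects)
  set.seed(.sub_seed(cfg, 4L))
  assay <- sample(c("in_house", "commercial_v2", "csf"), n, replace = TRUE,
                  prob = c(0.30, 0.38, 0.32))
  n_pos <- round(fraction_positive * n)
  pos <- rep(FALSE, n)
  if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
  up <- function(k) 1 + stats::runif(k, 0.05, 0.40)
  down <- function(k) 1 - stats::runif(k, 0.05, 0.50)
  out <- data.frame(subject_id = subjects$subject_id, assay = assay,
                    plasma_ptau181 = NA_real_, plasma_assay = NA_character_,
                    csf_ptau181 = NA_real_, csf_abeta42 = NA_real_,
                    csf_ttau = NA_real_, true_positive = pos,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (assay[i] == "in_house") {
      thr <- if (subjects$age[i] < 60) 10.5 else 13.3
      out$plasma_ptau181[i] <- thr * (if (pos[i]) up(1) else down(1))
      out$plasma_assay[i] <- "in_house"
    } else if (assay[i] == "commercial_v2") {
      out$plasma_ptau181[i] <- 2.2 * (if (pos[i]) up(1) else down(1))
      out$plasma_assay[i] <- "commercial_v2"
    } else {
      ttau <- max(stats::rnorm(1, 256, 130), 60)
      out$csf_ttau[i] <- ttau
      idx_bound <- 0.8 * (240 + 1.18 * ttau)   # Ab42 at which the index hits 0.8
      if (pos[i]) {
        out$csf_ptau181[i] <- 68 * up(1)
        out$csf_abeta42[i] <- idx_bound * down(1)
      } else {
        out$csf_ptau181[i] <- 68 * down(1)
        out$csf_abeta42[i] <- idx_bound * up(1)
      }
    }
  }
  out
}

#' Block-parcellation label atlas of the synthetic space
#'
#' Splits the grid into 4 x 4 x 2 rectangular parcels (masked downstream by
#' the grey-matter mask), named `blk_<x>_<y>_<z>`. Serves as a generic
#' integer-label atlas for region-level positivity statistics; parcels
#' overlapping the tau hotspots carry signal, central/inferior parcels act
#' as null ("deep grey") regions.
#'
#' @param cfg a [sim_config()].
#' @return A [label_atlas()].
#' @export
sim_atlas <- function(cfg) {
  gd <- cfg$grid_dims
  bx <- pmin(ceiling(seq_len(gd[1]) / (gd[1] / 4)), 4)
  by <- pmin(ceiling(seq_len(gd[2]) / (gd[2] / 4)), 4)
  bz <- pmin(ceiling(seq_len(gd[3]) / (gd[3] / 2)), 2)
  lab <- array(0L, dim = gd)
  cx <- slice.index(lab, 1); cy <- slice.index(lab, 2); cz <- slice.index(lab, 3)
  lab[] <- (bx[cx] - 1L) * 8L + (by[cy] - 1L) * 2L + bz[cz]
  nm <- character(32)
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    nm[(i - 1) * 8 + (j - 1) * 2 + k] <- sprintf("blk_%d_%d_%d", i, j, k)
  label_atlas(lab, stats::setNames(nm, as.character(1:32)), cfg$voxel_size_mm)
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper generating controls, athletes, the grey-matter mask
#' and the atlas from one config. Neuropsych and biofluid tables depend on
#' downstream quantities (% positivity) and are generated separately.
#'
#' @param cfg a [sim_config()].
#' @return `list(cfg, controls, athletes, gm_mask, atlas)`.
#' @export
simulate_cohort <- function(cfg) {
  list(cfg = cfg,
       controls = generate_controls(cfg),
       athletes = generate_athletes(cfg),
       gm_mask = sim_gm_mask(cfg),
       atlas = sim_atlas(cfg))
}

#' Write a simulated cohort to disk
#'
#' Exports per-subject NIfTI volumes, `subjects.csv`, and `truth.json`
#' (ground-truth parameters and per-subject labels) to a directory.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- rbind(
    cbind(cohort$controls$subjects,
          education = NA, scanner = NA, scan_window = NA,
          scan_duration_min = NA, tau_severity = NA),
    cohort$athletes$subjects)
  utils::write.csv(subs, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (i in seq_along(cohort$controls$gm))
    write_volume(cohort$controls$gm[[i]],
                 file.path(dir, paste0(cohort$controls$subjects$subject_id[i], "_gm.nii.gz")))
  for (i in seq_along(cohort$athletes$gm)) {
    id <- cohort$athletes$subjects$subject_id[i]
    write_volume(cohort$athletes$gm[[i]], file.path(dir, paste0(id, "_gm.nii.gz")))
    write_volume(cohort$athletes$suvr[[i]], file.path(dir, paste0(id, "_suvr.nii.gz")))
  }
  truth <- list(
    config = unclass(cohort$cfg),
    severity = cohort$athletes$truth$severity,
    subject_id = cohort$athletes$subjects$subject_id)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
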