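#' Run the full synthetic study pipeline
#'
#' Executes the whole analysis chain on a simulated cohort with known
#' ground truth: cohort generation, AD-biomarker gating, PET smoothing and
#' SUVR positivity, normative-model fitting on controls, athlete w-score
#' maps, mask-conditional w-score means, quartile assignment and region
#' statistics, neuropsychological composites, and the final inferential
#' block (paired t on tau-positive vs tau-negative mean w, partial Pearson
#' correlations of the composites with the tau measures).
#'
#' Every stage is deterministic given the config seed; the returned
#' manifest (config snapshot + seeds + per-stage n) suffices to re-execute
#' the run bit-identically.
#'
#' @param cfg a [sim_config()], or a path to a YAML/JSON file whose fields
#'   are `sim_config()` arguments.
#' @param fraction_biofluid_positive proportion of simulated athletes drawn
#'   AD-biomarker positive; the gate excludes them before analysis.
#' @param threshold,cmp SUVR positivity threshold and comparator.
#' @param boot compute BCa bootstrap CIs (paired difference and Table-2
#'   style correlation CIs).
#' @param regions run the per-region quartile extent regressions.
#' @param n_boot_paired,n_boot_corr,n_boot_regions bootstrap replicate
#'   counts (defaults: 2000 for the paired contrast and region
#'   regressions, 1000 for the correlation table).
#' @param bonferroni_m_corr Bonferroni family for the correlation table
#'   (default 6 = 3 composites x 2 tau measures).
#' @param out_dir optional directory; writes `analysis_report.json` and
#'   `manifest.json`.
#' @return A list of class `tauvbm_report`.
#' @export
run_pipeline <- function(cfg,
                         fraction_biofluid_positive = 0,
                         threshold = 1.30, cmp = ">=",
                         boot = TRUE, regions = TRUE,
                         n_boot_paired = 2000L, n_boot_corr = 1000L,
                         n_boot_regions = 2000L,
                         bonferroni_m_corr = 6L,
                         out_dir = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "sim_config"))
  manifest <- list(config = unclass(cfg), package_version = as.character(
    utils::packageVersion("tauvbm")), stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)

  ## simulate ----------------------------------------------------------
  controls <- generate_controls(cfg)
  athletes <- generate_athletes(cfg)
  gm_mask <- sim_gm_mask(cfg)
  atlas <- sim_atlas(cfg)
  note("simulate", n_controls = nrow(controls$subjects),
       n_athletes = nrow(athletes$subjects))

  ## gate --------------------------------------------------------------
  biofluids <- generate_biofluids(athletes$subjects, fraction_biofluid_positive, cfg)
  panels <- merge(athletes$subjects[, c("subject_id", "age")], biofluids,
                  by = "subject_id", sort = FALSE)
  panels$plasma_assay[is.na(panels$plasma_ptau181)] <- NA
  gate <- apply_gate(panels)
  keep <- athletes$subjects$subject_id %in% gate$included
  ath_sub <- athletes$subjects[keep, , drop = FALSE]
  ath_gm <- athletes$gm[keep]
  ath_suvr <- athletes$suvr[keep]
  n_ath <- nrow(ath_sub)
  note("gate", n_screened = nrow(athletes$subjects),
       n_excluded = length(gate$excluded), n_included = n_ath)

  ## pet: smooth -> threshold -> % positivity --------------------------
  pos_results <- vector("list", n_ath)
  pct_global <- gm_suvr_mean <- numeric(n_ath)
  region_counts <- matrix(NA_real_, n_ath, length(atlas$name_table),
                          dimnames = list(ath_sub$subject_id,
                                          unname(atlas$name_table)))
  suvr_smoothed <- vector("list", n_ath)
  for (i in seq_len(n_ath)) {
    k <- smoothing_kernel(ath_sub$scanner[i])
    sm <- smooth_volume(ath_suvr[[i]], k, boundary = "renorm", mask = gm_mask)
    suvr_smoothed[[i]] <- sm
    res <- threshold_positivity(sm, gm_mask, threshold = threshold, cmp = cmp)
    pos_results[[i]] <- res
    pp <- percent_positivity(res, atlas)
    pct_global[i] <- pp$global
    region_counts[i, ] <- pp$n_pos_by_region
    gm_suvr_mean[i] <- mean(sm$data[gm_mask], na.rm = TRUE)
  }
  note("pet", n_subjects = n_ath, threshold = threshold, cmp = cmp)

  ## normative model + w-scores ----------------------------------------
  model <- fit_normative(controls$gm, controls$subjects, fit_mask = gm_mask)
  wsum <- data.frame(subject_id = ath_sub$subject_id,
                     mean_w_pos = NA_real_, mean_w_neg = NA_real_,
                     n_vox_pos = NA_integer_, n_vox_neg = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_ath)) {
    w <- wscore_map(model, ath_gm[[i]], ath_sub$age[i], ath_sub$tiv[i])
    s <- extract_mask_means(w, pos_results[[i]]$positive_mask,
                            pos_results[[i]]$negative_mask)
    wsum$mean_w_pos[i] <- s$mean_w_pos; wsum$mean_w_neg[i] <- s$mean_w_neg
    wsum$n_vox_pos[i] <- s$n_vox_pos; wsum$n_vox_neg[i] <- s$n_vox_neg
  }
  note("wscore", n_subjects = n_ath,
       n_empty_positive = sum(wsum$n_vox_pos == 0))

  ## quartiles ----------------------------------------------------------
  assignment <- suppressMessages(
    assign_quartiles(pct_global, ids = ath_sub$subject_id))
  quartile_means <- mean_suvr_by_quartile(suvr_smoothed, assignment)
  region_table <- NULL
  if (regions) {
    extent <- data.frame(
      subject_id = rep(ath_sub$subject_id, times = ncol(region_counts)),
      region = rep(colnames(region_counts), each = n_ath),
      extent = as.vector(region_counts), stringsAsFactors = FALSE)
    region_table <- region_extent_regression(
      extent, assignment, ath_sub,
      n_boot = if (boot) n_boot_regions else 200L,
      seed = .sub_seed(cfg, 7L))
  }
  note("quartiles", sizes = assignment$sizes)

  ## composites ---------------------------------------------------------
  scores <- generate_neuropsych(ath_sub, pct_global, cfg)
  composites <- build_composites(scores)
  note("composites", n = nrow(composites))

  ## analyze ------------------------------------------------------------
  paired <- paired_t(wsum$mean_w_pos, wsum$mean_w_neg,
                     n_boot = if (boot) n_boot_paired else NULL,
                     seed = .sub_seed(cfg, 5L))
  covars <- cbind(age = ath_sub$age, education = ath_sub$education,
                  scanner = as.numeric(ath_sub$scanner == "HRRT"),
                  duration = ath_sub$scan_duration_min)
  corr_rows <- list()
  for (comp in c("memory", "speed", "executive")) {
    for (meas in c("pct_positivity", "gm_suvr")) {
      xv <- if (meas == "pct_positivity") pct_global else gm_suvr_mean
      pc <- partial_pearson(xv, composites[[comp]], covars,
                            n_boot = if (boot) n_boot_corr else NULL,
                            seed = .sub_seed(cfg, 6L))
      corr_rows[[paste(comp, meas, sep = ".")]] <- data.frame(
        composite = comp, tau_measure = meas, r = pc$r, n = pc$n,
        p_raw = pc$p_two_sided,
        ci_lo = if (is.null(pc$bca_ci)) NA_real_ else pc$bca_ci[1],
        ci_hi = if (is.null(pc$bca_ci)) NA_real_ else pc$bca_ci[2],
        stringsAsFactors = FALSE)
    }
  }
  corr_table <- do.call(rbind, corr_rows)
  corr_table$p_bonferroni <- bonferroni(corr_table$p_raw, bonferroni_m_corr)
  rownames(corr_table) <- NULL
  note("analyze", n_pairs = paired$n_pairs,
       n_corr = stats::setNames(corr_table$n, paste(corr_table$composite,
                                                    corr_table$tau_measure)))

  report <- structure(list(
    manifest = manifest,
    gate = gate$report,
    pct_positivity = stats::setNames(pct_global, ath_sub$subject_id),
    gm_suvr_mean = stats::setNames(gm_suvr_mean, ath_sub$subject_id),
    wscore_summary = wsum,
    paired = paired,
    quartiles = assignment,
    quartile_mean_suvr = quartile_means,
    region_table = region_table,
    composites = composites,
    correlations = corr_table,
    model = model),
    class = "tauvbm_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

#' @export
print.tauvbm_report <- function(x, ...) {
  st <- x$manifest$stages
  cat("== Synthetic tau-PET / w-score study report ==\n")
  cat(sprintf("Gate: %d screened, %d excluded, %d analyzed\n",
              st$gate$n_screened, st$gate$n_excluded, st$gate$n_included))
  cat(sprintf("Global %% positivity: median %.2f%% (range %.2f-%.2f)\n",
              stats::median(x$pct_positivity), min(x$pct_positivity),
              max(x$pct_positivity)))
  cat("Paired w-score contrast (tau+ vs tau-):\n  ")
  print(x$paired)
  cat("Quartiles: "); print(x$quartiles)
  cat("Composite ~ tau partial correlations:\n")
  print(x$correlations, digits = 3)
  invisible(x)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pr <- report$paired
  json <- list(
    gate = report$gate,
    paired = list(n_pairs = pr$n_pairs, mean_w_pos = pr$mean_a,
                  mean_w_neg = pr$mean_b, mean_diff = pr$mean_diff,
                  sd_pos = pr$sd_a, sd_neg = pr$sd_b,
                  t = pr$t_stat, p = pr$p_two_sided,
                  bca_ci = pr$bca_ci_diff),
    quartiles = list(sizes = report$quartiles$sizes,
                     cut_values = report$quartiles$cut_values),
    correlations = report$correlations,
    region_table = report$region_table,
    pct_positivity = as.list(report$pct_positivity))
  jsonlite::write_json(json, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Load a pipeline configuration file
#'
#' YAML (if the yaml package is installed) or JSON document whose top-level
#' fields are [sim_config()] arguments.
#'
#' @param path file path.
#' @return A `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  lst <- if (grepl("\\.json$", path)) jsonlite::fromJSON(txt)
         else if (requireNamespace("yaml", quietly = TRUE)) yaml::yaml.load(txt)
         else stop("load_config: YAML support requires the yaml package")
  do.call(sim_config, lst)
}
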