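#' Classify plasma p-tau181 for AD-biomarker positivity
#'
#' Applies the assay-specific thresholds with strict inequality. For the
#' in-house Simoa assay the threshold is age-dependent: > 10.5 pg/mL for
#' subjects under 60, > 13.3 pg/mL at 60 and above. The commercial
#' Advantage V2 kit uses > 2.2 pg/mL at any age.
#'
#' @param value plasma p-tau181 concentration (pg/mL, > 0).
#' @param assay `"in_house"` or `"commercial_v2"`.
#' @param age age in years; required for the in-house assay.
#' @return `"positive"` or `"negative"`.
#' @export
classify_plasma <- function(value, assay = c("in_house", "commercial_v2"), age = NULL) {
  assay <- match.arg(assay)
  if (!is.finite(value) || value <= 0)
    stop("classify_plasma: value must be a positive concentration, got ", value)
  if (assay == "in_house") {
    if (is.null(age) || is.na(age))
      stop("classify_plasma: in_house assay requires age (age-dependent threshold)")
    thr <- if (age < 60) 10.5 else 13.3
  } else {
    thr <- 2.2
  }
  if (value > thr) "positive" else "negative"
}

#' CSF amyloid-beta 42 to total-tau discriminant index
#'
#' The conventional discriminant ratio `Ab42 / (240 + 1.18 * t-tau)`; values
#' below 0.8 are consistent with Alzheimer-type pathology. The index
#' formula is pluggable in [classify_csf()] — this default is the widely
#' used one, not a certainty, and the choice is surfaced in reports.
#'
#' @param abeta42 CSF amyloid-beta 42 (pg/mL).
#' @param ttau CSF total tau (pg/mL).
#' @return The index value.
#' @export
csf_index_default <- function(abeta42, ttau) abeta42 / (240 + 1.18 * ttau)

#' Classify a CSF triplet for AD-biomarker positivity
#'
#' Positive iff CSF p-tau > 68 pg/mL AND the amyloid/t-tau index is < 0.8.
#' Both comparisons are strict.
#'
#' @param ptau,abeta42,ttau CSF p-tau181, amyloid-beta 42 and total tau
#'   (pg/mL, all > 0).
#' @param index_fn function of `(abeta42, ttau)` returning the discriminant
#'   index; defaults to [csf_index_default()].
#' @return `"positive"` or `"negative"`.
#' @export
classify_csf <- function(ptau, abeta42, ttau, index_fn = csf_index_default) {
  vals <- c(ptau = ptau, abeta42 = abeta42, ttau = ttau)
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad))
    stop("classify_csf: non-positive ", paste(names(vals)[bad], collapse = ", "))
  if (ptau > 68 && index_fn(abeta42, ttau) < 0.8) "positive" else "negative"
}

#' Apply the AD-biomarker exclusion gate to an athlete cohort
#'
#' A subject is excluded iff any available modality — plasma p-tau181 at the
#' assay-specific threshold, the CSF triplet, or a PET-pattern AD flag —
#' classifies positive at any visit. Subjects with multiple rows (visits)
#' are excluded if ANY visit is positive. Each exclusion records the rule
#' that fired. Subjects with neither a gateable panel nor a PET flag are an
#' error.
#'
#' @param panels data.frame with one row per subject-visit: `subject_id`,
#'   `age`, and any of `plasma_ptau181` + `plasma_assay`, the CSF columns
#'   `csf_ptau181`/`csf_abeta42`/`csf_ttau`, and logical `pet_ad_flag`.
#' @param index_fn CSF index function, see [classify_csf()].
#' @return `list(included, excluded, report)`: character vectors of subject
#'   ids (union = input set, disjoint) and a per-subject decision
#'   data.frame with the reason string.
#' @export
apply_gate <- function(panels, index_fn = csf_index_default) {
  stopifnot(is.data.frame(panels), "subject_id" %in% names(panels))
  if (!"pet_ad_flag" %in% names(panels)) panels$pet_ad_flag <- FALSE
  panels$pet_ad_flag[is.na(panels$pet_ad_flag)] <- FALSE
  ids <- unique(panels$subject_id)
  decision <- character(length(ids))
  reason <- character(length(ids))
  for (j in seq_along(ids)) {
    rows <- panels[panels$subject_id == ids[j], , drop = FALSE]
    gateable <- FALSE
    verdicts <- character(0)
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      if (!is.null(r$plasma_ptau181) && !is.na(r$plasma_ptau181)) {
        gateable <- TRUE
        v <- classify_plasma(r$plasma_ptau181, r$plasma_assay,
                             age = if ("age" %in% names(r)) r$age else NULL)
        if (v == "positive")
          verdicts <- c(verdicts, sprintf(
            "plasma %s %.4g pg/mL above threshold (visit %d)",
            r$plasma_assay, r$plasma_ptau181, k))
      }
      has_csf <- all(c("csf_ptau181", "csf_abeta42", "csf_ttau") %in% names(r)) &&
        !is.na(r$csf_ptau181) && !is.na(r$csf_abeta42) && !is.na(r$csf_ttau)
      if (has_csf) {
        gateable <- TRUE
        v <- classify_csf(r$csf_ptau181, r$csf_abeta42, r$csf_ttau, index_fn)
        if (v == "positive")
          verdicts <- c(verdicts, sprintf(
            "CSF p-tau %.4g > 68 and index < 0.8 (visit %d)", r$csf_ptau181, k))
      }
      if (isTRUE(r$pet_ad_flag)) {
        gateable <- TRUE
        verdicts <- c(verdicts, sprintf("tau-PET pattern suggestive of AD (visit %d)", k))
      }
    }
    if (!gateable)
      stop("apply_gate: subject ", ids[j],
           " has neither a gateable biofluid panel nor a PET AD flag")
    if (length(verdicts)) {
      decision[j] <- "excluded"; reason[j] <- paste(verdicts, collapse = "; ")
    } else {
      decision[j] <- "included"; reason[j] <- ""
    }
  }
  report <- data.frame(subject_id = ids, decision = decision, reason = reason,
                       stringsAsFactors = FALSE)
  list(included = ids[decision == "included"],
       excluded = ids[decision == "excluded"],
       report = report)
}

#' Worked screening cohort of 52 athletes
#'
#' A deterministic single-visit screening table of 52 athletes in which
#' five subjects fail the AD gate: one in-house plasma value of
#' 13.18 pg/mL (age below 60), three commercial V2 values of 7.4, 2.8 and
#' 2.5 pg/mL, and one subject flagged for an AD-like tau-PET retention
#' pattern (global grey-matter SUVR 2.73). The remaining 47 subjects carry
#' biomarker-negative panels. Used as the reference input for gate
#' validation; the flagged values are the cohort's printed screening
#' results.
#'
#' @return A data.frame of 52 rows suitable for [apply_gate()].
#' @export
example_screening_cohort <- function() {
  n <- 52L
  df <- data.frame(
    subject_id = sprintf("scr_%02d", seq_len(n)),
    age = rep(c(45, 52, 58, 63, 67), length.out = n),
    plasma_ptau181 = NA_real_, plasma_assay = NA_character_,
    csf_ptau181 = NA_real_, csf_abeta42 = NA_real_, csf_ttau = NA_real_,
    pet_ad_flag = FALSE, gm_suvr = NA_real_,
    stringsAsFactors = FALSE)
  # the five screen failures
  df$plasma_ptau181[1] <- 13.18; df$plasma_assay[1] <- "in_house"; df$age[1] <- 55
  df$plasma_ptau181[2] <- 7.4;  df$plasma_assay[2] <- "commercial_v2"
  df$plasma_ptau181[3] <- 2.8;  df$plasma_assay[3] <- "commercial_v2"
  df$plasma_ptau181[4] <- 2.5;  df$plasma_assay[4] <- "commercial_v2"
  df$pet_ad_flag[5] <- TRUE;    df$gm_suvr[5] <- 2.73
  # negative remainder: alternate assay routes, values below threshold
  for (i in 6:n) {
    route <- c("in_house", "commercial_v2", "csf")[1 + (i %% 3)]
    if (route == "in_house") {
      df$plasma_ptau181[i] <- 9.3; df$plasma_assay[i] <- "in_house"
    } else if (route == "commercial_v2") {
      df$plasma_ptau181[i] <- 1.1; df$plasma_assay[i] <- "commercial_v2"
    } else {
      df$csf_ptau181[i] <- 37.12; df$csf_abeta42[i] <- 926.43; df$csf_ttau[i] <- 255.87
    }
  }
  df
}
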