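#' Memory composite score
#'
#' Arithmetic mean of the available memory z-scores (RAVLT trials 1--5,
#' RAVLT long-delay recall, RVDLT trials 1--5). Higher = better. With the
#' two-test variant, only the RAVLT-trials and RVDLT z-scores enter.
#'
#' @param s a list/data.frame row with fields `ravlt_trials_z`,
#'   `ravlt_delay_z`, `rvdlt_trials_z` (missing values permitted).
#' @param min_present minimum number of inputs required; below it the
#'   composite is `NA` (never an error).
#' @param two_test if `TRUE`, use the 2-test RAVLT/RVDLT variant.
#' @return z-scale composite, or `NA`.
#' @export
memory_composite <- function(s, min_present = 2L, two_test = FALSE) {
  fields <- if (two_test) c("ravlt_trials_z", "rvdlt_trials_z")
            else c("ravlt_trials_z", "ravlt_delay_z", "rvdlt_trials_z")
  .mean_if_enough(s, fields, if (two_test) min(min_present, 2L) else min_present)
}

#' Attention / speed-of-processing composite score
#'
#' Mean of the available speed z-scores: TMT-A, digit span forward, Stroop
#' colour and word, SDMT written and oral.
#'
#' @inheritParams memory_composite
#' @param min_present minimum inputs required (default 4 of 6).
#' @return z-scale composite, or `NA`.
#' @export
speed_composite <- function(s, min_present = 4L) {
  .mean_if_enough(s, c("tmt_a_z", "digit_fwd_z", "stroop_color_z",
                       "stroop_word_z", "sdmt_written_z", "sdmt_oral_z"),
                  min_present)
}

#' Executive-function composite score
#'
#' The four WCST t-scores are averaged first, then that average, the digit
#' span backwards t-score and the TMT-B t-score are averaged — so the WCST
#' battery carries the joint weight of a single element (1/3 overall). The
#' composite stays on the t scale. All three elements (digit backwards,
#' a WCST average from at least `min_wcst` scores, TMT-B) are required;
#' otherwise the composite is `NA`.
#'
#' @param s row with `digit_bwd_t`, `tmt_b_t` and the WCST t-scores
#'   `wcst_err_t`, `wcst_persev_err_t`, `wcst_nonpersev_err_t`,
#'   `wcst_conceptual_t`.
#' @param min_wcst minimum WCST scores needed to form the WCST average.
#' @return t-scale composite, or `NA`.
#' @export
executive_composite <- function(s, min_wcst = 3L) {
  wcst <- .vals(s, c("wcst_err_t", "wcst_persev_err_t",
                     "wcst_nonpersev_err_t", "wcst_conceptual_t"))
  wcst <- wcst[!is.na(wcst)]
  db <- .vals(s, "digit_bwd_t"); tb <- .vals(s, "tmt_b_t")
  if (length(wcst) < min_wcst || is.na(db) || is.na(tb)) return(NA_real_)
  mean(c(db, mean(wcst), tb))
}

.vals <- function(s, fields) {
  out <- vapply(fields, function(f) {
    v <- s[[f]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[1])
  }, numeric(1))
  unname(out)
}

.mean_if_enough <- function(s, fields, min_present) {
  v <- .vals(s, fields)
  v <- v[!is.na(v)]
  if (length(v) < min_present) return(NA_real_)
  mean(v)
}

#' Build all three composites for a score table
#'
#' @param scores data.frame of test-level scores, one row per subject,
#'   with a `subject_id` column.
#' @param two_test_memory use the 2-test memory variant.
#' @return data.frame: subject_id, memory, speed, executive, and the
#'   number of inputs behind each composite.
#' @export
build_composites <- function(scores, two_test_memory = FALSE) {
  n <- nrow(scores)
  out <- data.frame(subject_id = scores$subject_id,
                    memory = NA_real_, speed = NA_real_, executive = NA_real_,
                    n_memory = 0L, n_speed = 0L, n_executive = 0L,
                    stringsAsFactors = FALSE)
  mem_f <- if (two_test_memory) c("ravlt_trials_z", "rvdlt_trials_z")
           else c("ravlt_trials_z", "ravlt_delay_z", "rvdlt_trials_z")
  spd_f <- c("tmt_a_z", "digit_fwd_z", "stroop_color_z", "stroop_word_z",
             "sdmt_written_z", "sdmt_oral_z")
  exe_f <- c("digit_bwd_t", "wcst_err_t", "wcst_persev_err_t",
             "wcst_nonpersev_err_t", "wcst_conceptual_t", "tmt_b_t")
  for (i in seq_len(n)) {
    r <- scores[i, ]
    out$memory[i] <- memory_composite(r, two_test = two_test_memory)
    out$speed[i] <- speed_composite(r)
    out$executive[i] <- executive_composite(r)
    out$n_memory[i] <- sum(!is.na(.vals(r, mem_f)))
    out$n_speed[i] <- sum(!is.na(.vals(r, spd_f)))
    out$n_executive[i] <- sum(!is.na(.vals(r, exe_f)))
  }
  out
}
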