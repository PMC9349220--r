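# Clinical rule engine: session-level dementia / non-dementia labels from
# CDR, MMSE and education-adjusted Logical Memory II, with eligibility
# filters and the "typical symptom" training-data criteria.

#' Education-dependent Logical Memory II cutoff
#'
#' Delayed-recall impairment is flagged relative to education: 0-9 years of
#' schooling use a cutoff of 2 points, 10-15 years use 4 points, 16 or more
#' years use 8 points. "Below the cutoff" always means `lm2 <= cutoff`;
#' "above" is strict.
#'
#' @param education_years Nonnegative integer vector of years of education.
#' @return Integer cutoff per element (2, 4 or 8).
#' @export
lm2_cutoff <- function(education_years) {
  if (any(!is.na(education_years) & education_years < 0))
    stop("education_years must be nonnegative")
  ifelse(education_years <= 9, 2L, ifelse(education_years <= 15, 4L, 8L))
}

.exclusion_reasons <- c("age_under_45", "gds_ge_10", "missing_data", "dialect")

#' Eligibility screen for one session
#'
#' A session is excluded when the participant is under 45, the GDS is 10 or
#' higher (to remove depressive pseudodementia), any required field or the
#' transcript is missing, or a strong dialect was flagged. The first
#' matching reason in that fixed order is reported.
#'
#' @param record One-row data frame (or list) with the clinical fields.
#' @param transcript Optional transcript text for this session; when given,
#'   an empty transcript counts as missing data.
#' @return List with `excluded` (logical) and `reason` (string or `NA`).
#' @export
apply_exclusions <- function(record, transcript = NULL) {
  get <- function(k) if (k %in% names(record)) record[[k]] else NA
  text <- if (!is.null(transcript)) transcript else get("text")
  if (!is.na(get("age")) && get("age") < 45)
    return(list(excluded = TRUE, reason = "age_under_45"))
  if (!is.na(get("gds")) && get("gds") >= 10)
    return(list(excluded = TRUE, reason = "gds_ge_10"))
  # education_years is required because the LM II cutoff depends on it
  required <- c("cdr", "mmse", "lm2", "gds", "age", "education_years")
  vals <- vapply(required, function(k) is.na(get(k)), logical(1))
  text_missing <- is.null(text) || is.na(text) || !nzchar(text)
  if (any(vals) || text_missing)
    return(list(excluded = TRUE, reason = "missing_data"))
  if (isTRUE(get("dialect_flag")))
    return(list(excluded = TRUE, reason = "dialect"))
  list(excluded = FALSE, reason = NA_character_)
}

# The three dementia rule patterns and the non-dementia pattern, evaluated
# on one session's scores. Kept as small predicates so the fallback region
# is exactly the complement (verified exhaustively in the tests).
.rule_dementia <- function(cdr, mmse, lm2, cutoff) {
  (cdr >= 1 & mmse <= 23) |
    (cdr >= 1 & mmse >= 24 & lm2 <= cutoff) |
    (cdr == 0.5 & mmse <= 23 & lm2 <= cutoff)
}
.rule_non_dementia <- function(cdr, mmse) cdr <= 0.5 & mmse >= 24

#' Assign the dementia / non-dementia label for one session
#'
#' Dementia is defined by (1) CDR >= 1 and MMSE <= 23, (2) CDR >= 1,
#' MMSE >= 24 and LM II at or below the education cutoff, or (3) CDR = 0.5,
#' MMSE <= 23 and LM II at or below the cutoff. Non-dementia (healthy
#' controls and MCI) is CDR <= 0.5 and MMSE >= 24. Any other score pattern
#' falls back to the recorded clinical diagnosis. Labels are per session:
#' repeat visits are labeled from that visit's scores.
#'
#' @param record One-row data frame (or list) with `cdr`, `mmse`, `lm2`,
#'   `education_years` and optionally `clinical_diagnosis`.
#' @return List with `label` (`"dementia"` or `"non_dementia"`) and
#'   `label_source` (`"rule"` or `"clinical_fallback"`).
#' @export
assign_label <- function(record) {
  cdr <- record[["cdr"]]; mmse <- record[["mmse"]]; lm2 <- record[["lm2"]]
  edu <- record[["education_years"]]
  if (anyNA(c(cdr, mmse, lm2, edu)))
    stop("assign_label requires cdr, mmse, lm2 and education_years")
  cutoff <- lm2_cutoff(edu)
  if (.rule_dementia(cdr, mmse, lm2, cutoff))
    return(list(label = "dementia", label_source = "rule"))
  if (.rule_non_dementia(cdr, mmse))
    return(list(label = "non_dementia", label_source = "rule"))
  cd <- record[["clinical_diagnosis"]]
  if (is.null(cd) || is.na(cd))
    stop("no labeling rule matches and clinical_diagnosis is missing",
         if (!is.null(record[["session_id"]]))
           paste0(" for session ", record[["session_id"]]) else "")
  list(label = cd, label_source = "clinical_fallback")
}

#' Training-data criteria
#'
#' Only sessions with typical score patterns train models: dementia with
#' CDR >= 1, MMSE <= 23 and LM II at or below the cutoff; MCI-type
#' non-dementia with CDR = 0.5, MMSE >= 24 and LM II at or below the
#' cutoff; or healthy-control non-dementia with CDR = 0, MMSE >= 24 and
#' LM II above the cutoff. Everything else is test-only.
#'
#' @param record One-row data frame (or list) with the score fields.
#' @param label The assigned label for this session.
#' @return Logical.
#' @export
is_training_eligible <- function(record, label) {
  cdr <- record[["cdr"]]; mmse <- record[["mmse"]]; lm2 <- record[["lm2"]]
  cutoff <- lm2_cutoff(record[["education_years"]])
  if (label == "dementia")
    return(cdr >= 1 && mmse <= 23 && lm2 <= cutoff)
  (cdr == 0.5 && mmse >= 24 && lm2 <= cutoff) ||
    (cdr == 0 && mmse >= 24 && lm2 > cutoff)
}

#' Label a whole cohort
#'
#' Runs the eligibility screen, the labeling rules and the training
#' criteria over every session of a cohort and returns the per-session
#' labeling report.
#'
#' @param cohort A cohort `data.frame` (see [as_cohort()]).
#' @return The cohort with added columns `excluded`, `exclusion_reason`,
#'   `label`, `label_source`, `training_eligible`; class `labeled_cohort`.
#' @export
label_cohort <- function(cohort) {
  n <- nrow(cohort)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)
  label <- rep(NA_character_, n)
  source <- rep(NA_character_, n)
  eligible <- rep(FALSE, n)
  for (i in seq_len(n)) {
    row <- as.list(cohort[i, ])
    ex <- apply_exclusions(row)
    excluded[i] <- ex$excluded
    reason[i] <- ex$reason
    if (ex$excluded) next
    lab <- assign_label(row)
    label[i] <- lab$label
    source[i] <- lab$label_source
    eligible[i] <- is_training_eligible(row, lab$label)
  }
  out <- as.data.frame(cohort)
  out$excluded <- excluded
  out$exclusion_reason <- reason
  out$label <- label
  out$label_source <- source
  out$training_eligible <- eligible
  class(out) <- c("labeled_cohort", "data.frame")
  out
}

#' Write the per-session labeling report
#'
#' @param labeled A `labeled_cohort` from [label_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labeling_report <- function(labeled, path) {
  cols <- c("subject_id", "session_id", "label", "label_source",
            "training_eligible", "excluded", "exclusion_reason")
  utils::write.csv(as.data.frame(labeled)[, cols], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.labeled_cohort <- function(x, ...) {
  kept <- !x$excluded
  cat(sprintf("Labeled cohort: %d sessions (%d excluded)\n",
              nrow(x), sum(x$excluded)))
  if (any(kept)) {
    tab <- table(x$label[kept])
    cat("  labels:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
    cat(sprintf("  training-eligible: %d of %d kept sessions\n",
                sum(x$training_eligible), sum(kept)))
  }
  invisible(x)
}
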