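#' Classify need for pediatric trauma center resources (NFPTCR)
#'
#' A patient is NFPTCR+ if any of five composite criteria fires; all time
#' and age boundaries are inclusive:
#'
#' * `transfusion` — emergent transfusion of any blood product within 4 h
#'   of arrival (`transfusion_hours <= 4`);
#' * `urgent_procedure` — any procedure from [procedure_types] within 72 h
#'   of arrival;
#' * `anesthesia_le5` — any general anesthesia or mechanical ventilation at
#'   age 5 years or younger;
#' * `icu` — admission from the emergency department to the ICU, or any
#'   ICU stay of at least 3 days (cumulative);
#' * `abuse` — physical child abuse report or investigation.
#'
#' Death is deliberately not a criterion; a patient who died in the ED with
#' no qualifying event classifies negative. Classification is a pure
#' function of the record.
#'
#' @param cohort Cohort data.frame (one or more records).
#' @return `data.frame` with columns `patient_id`, `positive` (logical) and
#'   the list-column `fired` (character vector of criterion labels, a
#'   subset of [nfptcr_criteria]); `positive` is true iff `fired` is
#'   non-empty.
#' @examples
#' vocab <- generate_vocabulary(10, seed = 1)
#' cohort <- generate_cohort(cohort_spec(50, seed = 2), vocab)
#' head(classify_nfptcr(cohort))
#' @export
classify_nfptcr <- function(cohort) {
  if (!is.data.frame(cohort)) abort_invalid("cohort must be a data.frame")
  n <- nrow(cohort)
  transfusion <- !is.na(cohort$transfusion_hours) &
    cohort$transfusion_hours <= 4
  urgent <- vapply(cohort$procedures, function(p) {
    if (length(p) == 0L) return(FALSE)
    parts <- strsplit(p, "@", fixed = TRUE)
    any(vapply(parts, function(x)
      x[1] %in% procedure_types && as.numeric(x[2]) <= 72, logical(1)))
  }, logical(1))
  anesthesia_le5 <- (cohort$anesthesia | cohort$mech_vent) &
    cohort$age_years <= 5L
  icu <- cohort$ed_disposition == "admit_icu" | cohort$icu_days >= 3L
  abuse <- cohort$abuse_flag

  fired_mat <- cbind(transfusion, urgent_procedure = urgent,
                     anesthesia_le5, icu, abuse)
  res <- data.frame(patient_id = cohort$patient_id,
                    positive = rowSums(fired_mat) > 0,
                    stringsAsFactors = FALSE)
  res$fired <- lapply(seq_len(n),
                      function(i) nfptcr_criteria[fired_mat[i, ]])
  res
}

#' NFPTCR prevalence in a cohort
#'
#' @param x Either a cohort data.frame (classified on the fly) or a
#'   [classify_nfptcr()] result.
#' @return List with `n_positive` (integer) and `fraction`
#'   (`n_positive / n`).
#' @export
nfptcr_prevalence <- function(x) {
  if (!is.data.frame(x) || nrow(x) == 0L)
    abort_invalid("cohort must be a non-empty data.frame")
  if (!"positive" %in% names(x)) x <- classify_nfptcr(x)
  n_pos <- sum(x$positive)
  list(n_positive = as.integer(n_pos), fraction = n_pos / nrow(x))
}

#' Write NFPTCR classifications to CSV
#'
#' Columns `patient_id,positive,fired`, `fired` `;`-separated.
#'
#' @param results A [classify_nfptcr()] result.
#' @param path File path.
#' @export
write_nfptcr_csv <- function(results, path) {
  out <- data.frame(patient_id = results$patient_id,
                    positive = results$positive,
                    fired = vapply(results$fired, paste, character(1),
                                   collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
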