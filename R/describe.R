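fmt_n_pct <- function(n, total) sprintf("%d (%d)", n, round(100 * n / total))
fmt_med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 2)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

#' Descriptive comparison of NFPTCR+ and NFPTCR- patients
#'
#' Builds the standard two-group descriptive table: n (%) per level for
#' categorical variables (sex, mechanism, ED disposition) with a Pearson
#' chi-square test (no continuity correction), and median (IQR) for
#' continuous variables (age, hospital hours, ICU days and the three
#' severity scores) with a Kruskal-Wallis test (tie-corrected; with two
#' groups this is the rank-sum test referred to chi-square with 1 df).
#'
#' @param cohort Cohort data.frame.
#' @param nfptcr_results Matching [classify_nfptcr()] result (defines the
#'   groups).
#' @param scores Matching [apply_scores()] result, or `NULL` to omit the
#'   score rows.
#' @return `data.frame` of class `cohort_summary` with columns
#'   `variable,level,nfptcr_pos,nfptcr_neg,statistic,p_value,test`; the
#'   test statistic and p-value are repeated across the level rows of a
#'   categorical variable. Group sizes are carried in attributes `n_pos`
#'   and `n_neg`.
#' @export
describe_cohort <- function(cohort, nfptcr_results, scores = NULL) {
  stopifnot(nrow(cohort) == nrow(nfptcr_results),
            all(cohort$patient_id == nfptcr_results$patient_id))
  grp <- nfptcr_results$positive
  if (!any(grp) || all(grp))
    abort("both NFPTCR groups must be non-empty", "pedtriage_degenerate_group")
  if (!is.null(scores)) {
    stopifnot(all(cohort$patient_id == scores$patient_id))
  }
  n_pos <- sum(grp)
  n_neg <- sum(!grp)

  rows <- list()
  add_cat <- function(name, values) {
    tab <- table(values, factor(grp, levels = c(TRUE, FALSE)))
    test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    for (lev in rownames(tab)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = name, level = lev,
        nfptcr_pos = fmt_n_pct(tab[lev, "TRUE"], n_pos),
        nfptcr_neg = fmt_n_pct(tab[lev, "FALSE"], n_neg),
        statistic = unname(test$statistic), p_value = test$p.value,
        test = "chi-square", stringsAsFactors = FALSE)
    }
  }
  add_cont <- function(name, values) {
    test <- stats::kruskal.test(values, factor(grp))
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = name, level = NA_character_,
      nfptcr_pos = fmt_med_iqr(values[grp]),
      nfptcr_neg = fmt_med_iqr(values[!grp]),
      statistic = unname(test$statistic), p_value = test$p.value,
      test = "kruskal-wallis", stringsAsFactors = FALSE)
  }

  add_cont("age_years", cohort$age_years)
  add_cat("sex", cohort$sex)
  add_cat("mechanism", cohort$mechanism)
  add_cat("ed_disposition", cohort$ed_disposition)
  add_cont("icu_days", cohort$icu_days)
  add_cont("hospital_hours", cohort$hospital_hours)
  if (!is.null(scores)) {
    add_cont("iss", scores$iss)
    add_cont("iciss_scaled", scores$iciss_scaled)
    add_cont("icass", scores$icass)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("cohort_summary", "data.frame")
  out
}
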