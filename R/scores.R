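#' Default critical-care episode rule
#'
#' Flags the patients counted as having had a critical-care episode when
#' deriving critical-care risk ratios: ICU admission from the emergency
#' department or any recorded ICU stay (>= 1 day), mechanical ventilation,
#' or in-hospital death. This rule is deliberately distinct from the NFPTCR
#' composite of [classify_nfptcr()], so that a score derived from it is not
#' evaluated against its own definition.
#'
#' @param cohort A cohort data.frame.
#' @return Logical vector, one element per patient.
#' @export
default_critcare_rule <- function(cohort) {
  cohort$ed_disposition == "admit_icu" | cohort$icu_days >= 1L |
    cohort$mech_vent | cohort$died
}

#' Derive per-code survival and critical-care risk ratios
#'
#' Tallies, for every distinct diagnosis code carried by at least
#' `min_count` patients of the derivation cohort, the number of carriers,
#' survivors and carriers with a critical-care episode, and forms
#' * the survival risk ratio `srr = n_survivors / n_patients` in \[0, 1\],
#'   the building block of ICISS, and
#' * the critical-care risk ratio `ccrr = 100 * n_critcare / n_patients` in
#'   \[0, 100\], the building block of ICASS.
#'
#' Duplicate codes within one patient are counted once. "Episodes" are a
#' patient-level indicator (a patient either had a critical-care episode or
#' did not), which keeps `ccrr` on the 0-100 scale.
#'
#' @param cohort Non-empty derivation cohort.
#' @param critcare_rule Function mapping the cohort to a logical
#'   critical-care indicator; default [default_critcare_rule()].
#' @param min_count Minimum number of carriers for a code to enter the
#'   table (default 1); rarer codes are treated as unseen at application
#'   time.
#' @return A `data.frame` of class `score_table` with columns
#'   `code_id,n_patients,n_survivors,n_critcare,srr,ccrr`, ordered by
#'   `code_id`, with attributes `years` (derivation years present) and
#'   `min_count`.
#' @examples
#' vocab <- generate_vocabulary(20, seed = 4)
#' cohort <- generate_cohort(cohort_spec(500, seed = 5), vocab)
#' head(derive_score_table(cohort))
#' @export
derive_score_table <- function(cohort, critcare_rule = default_critcare_rule,
                               min_count = 1L) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    abort_invalid("derivation cohort must be a non-empty cohort data.frame")
  if (min_count < 1L) abort_invalid("min_count must be >= 1")
  cc <- as.logical(critcare_rule(cohort))
  codes <- lapply(cohort$codes, unique)
  reps <- lengths(codes)
  long <- data.frame(code_id = unlist(codes, use.names = FALSE),
                     survived = rep(!cohort$died, reps),
                     critcare = rep(cc, reps),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n_survivors = survived,
                                n_critcare = critcare,
                                n_patients = rep(1L, nrow(long))) ~ code_id,
                          data = long, FUN = sum)
  agg <- agg[agg$n_patients >= min_count, , drop = FALSE]
  tab <- data.frame(code_id = agg$code_id,
                    n_patients = as.integer(agg$n_patients),
                    n_survivors = as.integer(agg$n_survivors),
                    n_critcare = as.integer(agg$n_critcare),
                    stringsAsFactors = FALSE)
  tab$srr <- tab$n_survivors / tab$n_patients
  tab$ccrr <- 100 * tab$n_critcare / tab$n_patients
  tab <- tab[order(tab$code_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "years") <- sort(unique(cohort$year))
  attr(tab, "min_count") <- as.integer(min_count)
  class(tab) <- c("score_table", "data.frame")
  tab
}

resolve_codes <- function(codes, table, unseen_policy, what) {
  if (!unseen_policy %in% c("neutral", "cohort_mean", "strict"))
    abort_invalid("unseen_policy must be one of 'neutral', 'cohort_mean', 'strict'")
  codes <- unique(codes)
  if (length(codes) == 0L)
    abort_invalid("record must carry at least one diagnosis code")
  idx <- match(codes, table$code_id)
  val <- table[[what]][idx]
  unseen <- is.na(idx)
  if (any(unseen)) {
    if (unseen_policy == "neutral") {
      val[unseen] <- if (what == "srr") 1 else 0
    } else if (unseen_policy == "cohort_mean") {
      val[unseen] <- mean(table[[what]])
    } else if (unseen_policy == "strict") {
      val <- val[!unseen]
      if (length(val) == 0L)
        abort(paste0("unresolvable score: all codes unseen (",
                     paste(codes, collapse = ", "), ")"),
              "pedtriage_unresolvable_score")
    } else {
      abort_invalid("unseen_policy must be one of 'neutral', 'cohort_mean', 'strict'")
    }
  }
  val
}

extract_codes <- function(record) {
  if (is.character(record)) return(record)
  if (is.data.frame(record) && nrow(record) == 1L && "codes" %in% names(record))
    return(record$codes[[1]])
  abort_invalid("record must be a character vector of code ids or a one-row cohort data.frame")
}

#' Per-patient ICISS on the inverted 0-100 scale
#'
#' The conventional ICISS is the product of the survival risk ratios of the
#' patient's distinct diagnosis codes (an estimated survival probability).
#' It is reported here inverted and rescaled, `(1 - prod(srr)) * 100`, so
#' that like ISS and ICASS, higher values indicate greater severity on a
#' 0-100 scale. `variant = "worst"` uses the single worst SRR instead of
#' the product.
#'
#' @param record Character vector of code ids, or a one-row cohort
#'   data.frame.
#' @param table A [derive_score_table()] result.
#' @param unseen_policy How codes absent from the table contribute:
#'   `"neutral"` (srr 1 / ccrr 0, i.e. no severity; default),
#'   `"cohort_mean"` (the table's mean ratio), or `"strict"` (drop them and
#'   error if none remain).
#' @param variant `"product"` (default) or `"worst"`.
#' @return Numeric score in \[0, 100\].
#' @examples
#' tab <- data.frame(code_id = c("A", "B"), n_patients = c(10L, 10L),
#'                   n_survivors = c(9L, 8L), n_critcare = c(0L, 0L),
#'                   srr = c(0.9, 0.8), ccrr = c(0, 0))
#' score_iciss(c("A", "B"), tab)  # 28
#' @export
score_iciss <- function(record, table, unseen_policy = "neutral",
                        variant = c("product", "worst")) {
  variant <- match.arg(variant)
  srr <- resolve_codes(extract_codes(record), table, unseen_policy, "srr")
  surv <- if (variant == "product") prod(srr) else min(srr)
  (1 - surv) * 100
}

#' Per-patient ICASS
#'
#' A patient's ICASS is the maximum critical-care risk ratio over their
#' distinct diagnosis codes: a patient whose two diagnoses carry risk
#' ratios 45 and 60 scores 60.
#'
#' @inheritParams score_iciss
#' @return Numeric score in \[0, 100\].
#' @export
score_icass <- function(record, table, unseen_policy = "neutral") {
  ccrr <- resolve_codes(extract_codes(record), table, unseen_policy, "ccrr")
  max(ccrr)
}

#' Score a whole application cohort
#'
#' Applies a derived score table to every patient of an application cohort,
#' producing ISS (from the AIS profile), scaled ICISS and ICASS per
#' patient, in input order. Warns (but proceeds) if the application cohort
#' shares calendar years with the table's derivation cohort, since a
#' temporal hold-out is the intended design.
#'
#' @param cohort Application cohort data.frame.
#' @param table A [derive_score_table()] result.
#' @inheritParams score_iciss
#' @return `data.frame` with columns `patient_id,iss,iciss_scaled,icass`.
#' @export
apply_scores <- function(cohort, table, unseen_policy = "neutral",
                         variant = c("product", "worst")) {
  variant <- match.arg(variant)
  if (nrow(cohort) == 0L)
    return(data.frame(patient_id = character(0), iss = integer(0),
                      iciss_scaled = numeric(0), icass = numeric(0),
                      stringsAsFactors = FALSE))
  dy <- attr(table, "years")
  if (!is.null(dy) && any(cohort$year %in% dy))
    warning("application cohort shares years with the derivation cohort")
  scores <- data.frame(
    patient_id = cohort$patient_id,
    iss = vapply(cohort$ais_profile, compute_iss, integer(1)),
    iciss_scaled = NA_real_, icass = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort))) {
    codes <- cohort$codes[[i]]
    res <- tryCatch(
      list(iciss = score_iciss(codes, table, unseen_policy, variant),
           icass = score_icass(codes, table, unseen_policy)),
      pedtriage_unresolvable_score = function(e)
        abort(paste0(conditionMessage(e), " [patient ",
                     cohort$patient_id[i], "]"),
              "pedtriage_unresolvable_score"))
    scores$iciss_scaled[i] <- res$iciss
    scores$icass[i] <- res$icass
  }
  scores
}

#' Read or write a score-table CSV
#'
#' Columns `code_id,n_patients,n_survivors,n_critcare,srr,ccrr`; derivation
#' metadata (years, min_count) travels in a JSON sidecar written next to
#' the CSV as `<path>.meta.json`.
#'
#' @param table A [derive_score_table()] result.
#' @param path File path of the CSV.
#' @return `read_score_table_csv` returns the table; the writer returns
#'   `path` invisibly.
#' @export
write_score_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "")
  meta <- list(years = attr(table, "years") %||% integer(0),
               min_count = attr(table, "min_count") %||% 1L)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_score_table_csv
#' @export
read_score_table_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(code_id = "character"))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(tab, "years") <- as.integer(meta$years)
    attr(tab, "min_count") <- as.integer(meta$min_count)
  }
  class(tab) <- c("score_table", "data.frame")
  tab
}
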