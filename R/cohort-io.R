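format_ais <- function(prof) {
  if (length(prof) == 0L) return("")
  nz <- prof[prof > 0]
  if (length(nz) == 0L) return("")
  paste0(names(nz), ":", nz, collapse = ";")
}

parse_ais <- function(s, row) {
  prof <- integer(length(body_regions))
  names(prof) <- body_regions
  if (is.na(s) || !nzchar(s)) return(integer(0))
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  for (p in parts) {
    if (length(p) != 2L || !p[1] %in% body_regions)
      abort_parse(sprintf("row %d, field ais_profile: malformed token '%s'",
                          row, paste(p, collapse = ":")))
    sev <- suppressWarnings(as.integer(p[2]))
    if (is.na(sev) || sev < 0L || sev > 6L)
      abort_parse(sprintf("row %d, field ais_profile: severity out of 0..6", row))
    prof[p[1]] <- sev
  }
  prof
}

parse_procs <- function(s, row) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  for (tok in toks) {
    p <- strsplit(tok, "@", fixed = TRUE)[[1]]
    hours <- suppressWarnings(as.numeric(p[2]))
    if (length(p) != 2L || !p[1] %in% procedure_types ||
        is.na(hours) || hours < 0)
      abort_parse(sprintf("row %d, field procedures: malformed token '%s'",
                          row, tok))
  }
  toks
}

#' Write or read a cohort CSV
#'
#' One row per patient; columns
#' `patient_id,year,age_years,sex,mechanism,codes,ais_profile,transfusion_hours,procedures,anesthesia,mech_vent,ed_disposition,icu_days,abuse_flag,died,hospital_hours`.
#' `codes` is a `;`-separated list of code ids; `procedures` holds
#' `;`-separated `type@hours` tokens (types from [procedure_types]);
#' `ais_profile` holds `;`-separated `region:severity` tokens for the
#' non-zero regions; absent numerics are written empty. `read_cohort_csv`
#' validates every row and reports the first malformed row and field;
#' `read(write(cohort))` reproduces the cohort field-for-field.
#'
#' @param cohort A cohort data.frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort; `write_cohort_csv` returns
#'   `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(
    patient_id = cohort$patient_id,
    year = cohort$year,
    age_years = cohort$age_years,
    sex = cohort$sex,
    mechanism = cohort$mechanism,
    codes = vapply(cohort$codes, paste, character(1), collapse = ";"),
    ais_profile = vapply(cohort$ais_profile, format_ais, character(1)),
    transfusion_hours = cohort$transfusion_hours,
    procedures = vapply(cohort$procedures, paste, character(1),
                        collapse = ";"),
    anesthesia = cohort$anesthesia,
    mech_vent = cohort$mech_vent,
    ed_disposition = cohort$ed_disposition,
    icu_days = cohort$icu_days,
    abuse_flag = cohort$abuse_flag,
    died = cohort$died,
    hospital_hours = cohort$hospital_hours,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), "pedtriage_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), cohort_columns()))
    abort_parse(paste0("cohort CSV must have columns ",
                       paste(cohort_columns(), collapse = ",")))
  n <- nrow(raw)
  if (n == 0L) return(empty_cohort())

  num_field <- function(field, allow_na = FALSE) {
    x <- raw[[field]]
    x[!nzchar(x)] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      abort_parse(sprintf("row %d, field %s: not a number", bad[1], field))
    if (!allow_na && anyNA(v))
      abort_parse(sprintf("row %d, field %s: missing value",
                          which(is.na(v))[1], field))
    neg <- which(v < 0)
    if (length(neg))
      abort_parse(sprintf("row %d, field %s: negative value", neg[1], field))
    v
  }
  lgl_field <- function(field) {
    x <- toupper(raw[[field]])
    bad <- which(!x %in% c("TRUE", "FALSE"))
    if (length(bad))
      abort_parse(sprintf("row %d, field %s: expected TRUE/FALSE",
                          bad[1], field))
    x == "TRUE"
  }

  cohort <- data.frame(
    patient_id = raw$patient_id,
    year = as.integer(num_field("year")),
    age_years = as.integer(num_field("age_years")),
    sex = raw$sex,
    mechanism = raw$mechanism,
    transfusion_hours = num_field("transfusion_hours", allow_na = TRUE),
    anesthesia = lgl_field("anesthesia"),
    mech_vent = lgl_field("mech_vent"),
    ed_disposition = raw$ed_disposition,
    icu_days = as.integer(num_field("icu_days")),
    abuse_flag = lgl_field("abuse_flag"),
    died = lgl_field("died"),
    hospital_hours = num_field("hospital_hours"),
    stringsAsFactors = FALSE
  )
  codes <- strsplit(raw$codes, ";", fixed = TRUE)
  empty <- which(vapply(codes, length, integer(1)) == 0L)
  if (length(empty))
    abort_parse(sprintf("row %d, field codes: empty code list", empty[1]))
  cohort$codes <- codes
  cohort$ais_profile <- lapply(seq_len(n),
                               function(i) parse_ais(raw$ais_profile[i], i))
  cohort$procedures <- lapply(seq_len(n),
                              function(i) parse_procs(raw$procedures[i], i))
  bad_disp <- which(!cohort$ed_disposition %in%
                      c("home", "admit_ward", "admit_icu", "transfer",
                        "died_ed"))
  if (length(bad_disp))
    abort_parse(sprintf("row %d, field ed_disposition: unknown category '%s'",
                        bad_disp[1], cohort$ed_disposition[bad_disp[1]]))
  bad_icu <- which(cohort$ed_disposition == "admit_icu" & cohort$icu_days < 1L)
  if (length(bad_icu))
    abort_parse(sprintf("row %d, field icu_days: admit_icu requires icu_days >= 1",
                        bad_icu[1]))
  cohort[, cohort_columns()]
}
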