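# fixture builders: minimal valid patient records assembled in code

full_profile <- function(...) {
  prof <- stats::setNames(integer(length(body_regions)), body_regions)
  vals <- c(...)
  prof[names(vals)] <- as.integer(vals)
  prof
}

patient_record <- function(patient_id = "P1", year = 2019L, age_years = 8L,
                           sex = "M", mechanism = "other_blunt",
                           codes = "SYN0001",
                           ais_profile = full_profile(head_neck = 2),
                           transfusion_hours = NA_real_,
                           procedures = character(0),
                           anesthesia = FALSE, mech_vent = FALSE,
                           ed_disposition = "admit_ward", icu_days = 0L,
                           abuse_flag = FALSE, died = FALSE,
                           hospital_hours = 24) {
  rec <- data.frame(patient_id = patient_id, year = as.integer(year),
                    age_years = as.integer(age_years), sex = sex,
                    mechanism = mechanism,
                    transfusion_hours = transfusion_hours,
                    anesthesia = anesthesia, mech_vent = mech_vent,
                    ed_disposition = ed_disposition,
                    icu_days = as.integer(icu_days),
                    abuse_flag = abuse_flag, died = died,
                    hospital_hours = hospital_hours,
                    stringsAsFactors = FALSE)
  rec$codes <- list(codes)
  rec$ais_profile <- list(ais_profile)
  rec$procedures <- list(procedures)
  rec[, pedtriage:::cohort_columns()]
}

bind_records <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# a small derivation cohort yielding known per-code tallies:
# code_id -> c(n_patients, n_critcare, n_deaths)
planted_cohort <- function(tallies, year = 2015L) {
  recs <- list()
  pid <- 0L
  for (code in names(tallies)) {
    n <- tallies[[code]][1]
    n_cc <- tallies[[code]][2]
    n_die <- if (length(tallies[[code]]) > 2) tallies[[code]][3] else 0L
    for (i in seq_len(n)) {
      pid <- pid + 1L
      recs[[pid]] <- patient_record(
        patient_id = sprintf("T%04d", pid), year = year, codes = code,
        icu_days = if (i <= n_cc) 1L else 0L,
        died = i <= n_die)
    }
  }
  do.call(bind_records, recs)
}

# independent brute-force AUC: count concordant positive-negative pairs,
# ties half
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
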