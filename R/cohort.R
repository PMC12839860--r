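#' Specify a synthetic registry cohort
#'
#' Bundles the sampling parameters for [generate_cohort()]. The defaults
#' emulate the marginal structure of a national pediatric trauma registry:
#' ages integer-uniform 0-15, mechanism mix dominated by blunt accidental
#' injury with small abuse and penetrating fractions, and roughly one in six
#' patients experiencing a critical-care episode under the default
#' vocabulary.
#'
#' @param n_patients Number of patients (>= 0).
#' @param years Calendar years patients are spread over (uniformly unless
#'   `year_weights` is given).
#' @param seed Integer seed; all randomness flows from it through a single
#'   generator stream.
#' @param max_codes_per_patient Cap on distinct diagnosis codes per patient.
#' @param code_count_p Success probability of the truncated geometric
#'   distribution of the per-patient code count (count = 1 + geometric,
#'   capped); larger values mean fewer codes.
#' @param p_female Probability of female sex.
#' @param mechanism_mix Named probabilities over
#'   `c("abuse", "penetrating", "transport", "other_blunt")`.
#' @param age_range Inclusive integer age range in years.
#' @param event_mix Named probabilities over the qualifying event planted
#'   for a critical-care patient: `transfusion` (within 4 h),
#'   `urgent_procedure` (within 72 h), `anesthesia` (general anesthesia,
#'   only meaningful at age <= 5; older patients fall back to
#'   `urgent_procedure`), `icu3` (ICU stay >= 3 days), `abuse` (physical
#'   child abuse report).
#' @param background_event_rate Probability that a patient *without* a
#'   critical-care episode nevertheless has one qualifying event planted.
#' @param out_of_window_rate Probability of planting an additional
#'   non-qualifying event (transfusion after 4 h or procedure after 72 h)
#'   to exercise the timeframe filters.
#' @param icu_admit_share Among critical-care episodes, the share realized
#'   as an ICU admission from the emergency department (the remainder are
#'   realized as mechanical ventilation on the ward).
#' @param year_weights Optional sampling weights over `years`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        years = 2014:2019,
                        seed = 1L,
                        max_codes_per_patient = 6L,
                        code_count_p = 0.5,
                        p_female = 0.63,
                        mechanism_mix = c(abuse = 0.013, penetrating = 0.019,
                                          transport = 0.316,
                                          other_blunt = 0.652),
                        age_range = c(0L, 15L),
                        event_mix = c(transfusion = 0.20,
                                      urgent_procedure = 0.30,
                                      anesthesia = 0.15,
                                      icu3 = 0.25,
                                      abuse = 0.10),
                        background_event_rate = 0.01,
                        out_of_window_rate = 0.05,
                        icu_admit_share = 0.65,
                        year_weights = NULL) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0)
    abort_invalid("n_patients must be a single non-negative integer")
  if (length(years) < 1L) abort_invalid("years must be non-empty")
  if (max_codes_per_patient < 1L)
    abort_invalid("max_codes_per_patient must be >= 1")
  stopifnot(setequal(names(mechanism_mix),
                     c("abuse", "penetrating", "transport", "other_blunt")),
            setequal(names(event_mix),
                     c("transfusion", "urgent_procedure", "anesthesia",
                       "icu3", "abuse")),
            code_count_p > 0, code_count_p <= 1,
            background_event_rate >= 0, background_event_rate <= 1,
            out_of_window_rate >= 0, out_of_window_rate <= 1)
  spec <- list(n_patients = as.integer(n_patients),
               years = as.integer(years),
               seed = as.integer(seed),
               max_codes_per_patient = as.integer(max_codes_per_patient),
               code_count_p = code_count_p,
               p_female = p_female,
               mechanism_mix = mechanism_mix / sum(mechanism_mix),
               age_range = as.integer(age_range),
               event_mix = event_mix / sum(event_mix),
               background_event_rate = background_event_rate,
               out_of_window_rate = out_of_window_rate,
               icu_admit_share = icu_admit_share,
               year_weights = year_weights)
  class(spec) <- "cohort_spec"
  spec
}

empty_cohort <- function() {
  cohort <- data.frame(patient_id = character(0), year = integer(0),
                       age_years = integer(0), sex = character(0),
                       mechanism = character(0),
                       transfusion_hours = numeric(0),
                       anesthesia = logical(0), mech_vent = logical(0),
                       ed_disposition = character(0), icu_days = integer(0),
                       abuse_flag = logical(0), died = logical(0),
                       hospital_hours = numeric(0),
                       stringsAsFactors = FALSE)
  cohort$codes <- list()
  cohort$ais_profile <- list()
  cohort$procedures <- list()
  cohort[, cohort_columns()]
}

cohort_columns <- function() {
  c("patient_id", "year", "age_years", "sex", "mechanism", "codes",
    "ais_profile", "transfusion_hours", "procedures", "anesthesia",
    "mech_vent", "ed_disposition", "icu_days", "abuse_flag", "died",
    "hospital_hours")
}

#' Generate a synthetic trauma-registry cohort
#'
#' Samples patient records whose outcomes are driven by the latent
#' propensities of the diagnosis codes they carry, so that risk ratios
#' derived downstream recover known quantities:
#'
#' * each patient carries 1..`max_codes_per_patient` distinct codes (count
#'   truncated-geometric, codes drawn uniformly without replacement);
#' * a critical-care episode occurs with probability
#'   \eqn{1 - \prod_j (1 - p^{(j)}_{cc})} over the patient's codes, and is
#'   realized as an ICU admission from the ED (with >= 1 ICU day) or as
#'   mechanical ventilation, so the default critical-care rule of
#'   [derive_score_table()] fires exactly for these patients;
#' * death occurs with marginal probability
#'   \eqn{1 - \prod_j p^{(j)}_{surv}}, nested within critical-care episodes
#'   (a child who dies in hospital is taken to have received critical
#'   care); this requires per-code `p_critcare >= 1 - p_survive`, which the
#'   default vocabulary guarantees — configurations violating it have their
#'   conditional death probability capped at 1;
#' * every critical-care patient additionally gets at least one qualifying
#'   trauma-center resource event (per `event_mix`) with a timestamp inside
#'   its window; patients without an episode get qualifying events only at
#'   `background_event_rate`, and non-qualifying (late) events at
#'   `out_of_window_rate`;
#' * the AIS profile is the per-region maximum of the carried codes' AIS
#'   severities.
#'
#' The cohort is a pure function of `(spec, vocabulary)`.
#'
#' @param spec A [cohort_spec()].
#' @param vocabulary A vocabulary from [generate_vocabulary()] (non-empty).
#' @return A `data.frame` with one row per patient and the columns listed in
#'   the cohort CSV interface (see [write_cohort_csv()]); `codes`,
#'   `ais_profile` and `procedures` are list-columns.
#' @examples
#' vocab <- generate_vocabulary(30, seed = 2)
#' cohort <- generate_cohort(cohort_spec(100, seed = 3), vocab)
#' table(cohort$ed_disposition)
#' @export
generate_cohort <- function(spec, vocabulary) {
  if (!inherits(spec, "cohort_spec")) abort_invalid("spec must be a cohort_spec")
  validate_vocabulary(vocabulary)
  n <- spec$n_patients
  if (n == 0L) return(empty_cohort())

  withr::with_seed(spec$seed, {
    nv <- nrow(vocabulary)
    kmax <- min(spec$max_codes_per_patient, nv)
    k <- pmin(1L + stats::rgeom(n, spec$code_count_p), kmax)
    code_idx <- lapply(k, function(ki) sort(sample.int(nv, ki)))

    age <- sample(spec$age_range[1]:spec$age_range[2], n, replace = TRUE)
    sex <- ifelse(stats::runif(n) < spec$p_female, "F", "M")
    mech <- sample(names(spec$mechanism_mix), n, replace = TRUE,
                   prob = spec$mechanism_mix)
    yw <- spec$year_weights %||% rep(1, length(spec$years))
    year <- spec$years[sample.int(length(spec$years), n, replace = TRUE,
                                  prob = yw)]

    p_cc <- vapply(code_idx, function(ix)
      1 - prod(1 - vocabulary$p_critcare[ix]), numeric(1))
    p_die <- vapply(code_idx, function(ix)
      1 - prod(vocabulary$p_survive[ix]), numeric(1))

    is_cc <- stats::runif(n) < p_cc
    # deaths nested within critical-care episodes; marginal P(death) = p_die
    # provided p_cc >= p_die (capped otherwise)
    died <- logical(n)
    died[is_cc] <- stats::runif(sum(is_cc)) <
      pmin(1, p_die[is_cc] / pmax(p_cc[is_cc], .Machine$double.eps))

    # critical-care realization
    transfusion_hours <- rep(NA_real_, n)
    procedures <- rep(list(character(0)), n)
    anesthesia <- logical(n)
    mech_vent <- logical(n)
    abuse_flag <- logical(n)
    icu_days <- integer(n)

    icu_adm <- is_cc & stats::runif(n) < spec$icu_admit_share
    mech_vent[is_cc & !icu_adm] <- TRUE
    icu_days[icu_adm] <- 1L + stats::rpois(sum(icu_adm), 1.3)

    # planted qualifying event
    ev <- sample(names(spec$event_mix), n, replace = TRUE,
                 prob = spec$event_mix)
    ev[ev == "anesthesia" & age > 5L] <- "urgent_procedure"
    plant <- is_cc | stats::runif(n) < spec$background_event_rate
    pt <- function(type) which(plant & ev == type)
    i <- pt("transfusion")
    transfusion_hours[i] <- round(stats::runif(length(i), 0, 4), 2)
    i <- pt("urgent_procedure")
    procedures[i] <- paste0(sample(procedure_types, length(i), replace = TRUE),
                            "@", round(stats::runif(length(i), 0, 72), 2))
    i <- pt("anesthesia")
    anesthesia[i] <- TRUE
    i <- pt("icu3")
    icu_days[i] <- pmax(icu_days[i], 3L)
    i <- pt("abuse")
    abuse_flag[i] <- TRUE

    # deliberately out-of-window events exercise the timeframe filters
    oow <- stats::runif(n) < spec$out_of_window_rate
    late_tx <- oow & is.na(transfusion_hours) & stats::runif(n) < 0.5
    transfusion_hours[late_tx] <- round(stats::runif(sum(late_tx), 4.01, 48), 2)
    late_pr <- which(oow & !late_tx)
    late_tok <- paste0(sample(procedure_types, length(late_pr), replace = TRUE),
                       "@", round(stats::runif(length(late_pr), 72.01, 240), 2))
    procedures[late_pr] <- Map(c, procedures[late_pr], late_tok)

    # incidental anesthesia in older children never fires the age-gated rule
    anesthesia[!is_cc & age >= 6L & stats::runif(n) < 0.08] <- TRUE

    ed_disposition <- rep("admit_ward", n)
    ed_disposition[icu_adm] <- "admit_icu"
    noncc <- which(!is_cc)
    ed_disposition[noncc] <- sample(c("home", "admit_ward", "transfer"),
                                    length(noncc), replace = TRUE,
                                    prob = c(0.20, 0.65, 0.15))
    # some deaths occur in the ED before ICU admission; keep only where the
    # planted qualifying event survives the change
    ded <- which(died & !icu_adm & ev %in% c("transfusion",
                                             "urgent_procedure", "abuse") &
                   stats::runif(n) < 0.25)
    ed_disposition[ded] <- "died_ed"
    icu_days[ded] <- 0L

    hospital_hours <- numeric(n)
    hospital_hours[is_cc] <- round(stats::rlnorm(sum(is_cc), log(62), 0.8), 1)
    hospital_hours[!is_cc] <- round(stats::rlnorm(sum(!is_cc), log(18), 0.8), 1)
    hospital_hours[ded] <- round(stats::runif(length(ded), 0.5, 6), 1)
    hospital_hours[ed_disposition == "home"] <-
      round(stats::runif(sum(ed_disposition == "home"), 1, 12), 1)

    ais_profile <- lapply(code_idx, function(ix) {
      prof <- integer(length(body_regions))
      names(prof) <- body_regions
      sev <- tapply(vocabulary$ais_severity[ix], vocabulary$body_region[ix],
                    max)
      prof[names(sev)] <- as.integer(sev)
      prof
    })

    cohort <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                         year = year, age_years = as.integer(age), sex = sex,
                         mechanism = mech,
                         transfusion_hours = transfusion_hours,
                         anesthesia = anesthesia, mech_vent = mech_vent,
                         ed_disposition = ed_disposition,
                         icu_days = icu_days, abuse_flag = abuse_flag,
                         died = died, hospital_hours = hospital_hours,
                         stringsAsFactors = FALSE)
    cohort$codes <- lapply(code_idx, function(ix) vocabulary$code_id[ix])
    cohort$ais_profile <- ais_profile
    cohort$procedures <- procedures
    rownames(cohort) <- NULL
    cohort[, cohort_columns()]
  })
}
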