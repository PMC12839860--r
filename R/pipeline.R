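#' Configure a derive-apply-evaluate study run
#'
#' Mirrors the temporal-validation design of the analysis: risk ratios are
#' derived on the `derivation_years` cohort and applied to the held-out
#' `application_year` cohort, after excluding patients above
#' `max_age_years` or (optionally) without a computable ISS.
#'
#' @param derivation_years Years of the derivation cohort.
#' @param application_year Single held-out year (must not be among the
#'   derivation years).
#' @param max_age_years Inclusion cut-off; patients older are excluded
#'   (default 15, i.e. children 15 and younger).
#' @param require_iss Exclude patients whose AIS profile is missing (no
#'   computable ISS)?
#' @param unseen_policy,min_count,iciss_variant Score policies, see
#'   [score_iciss()] and [derive_score_table()].
#' @param thresholds Threshold grid for the operating-characteristics
#'   table.
#' @param threshold_mode `"strict_greater"` or `"geq"`.
#' @param seed Integer seed used when the run simulates its own cohort.
#' @param n_patients,n_codes Size of the simulated registry when no cohort
#'   is supplied.
#' @param outdir Output directory for [run_study()].
#' @return List of class `run_config`.
#' @export
run_config <- function(derivation_years = 2014:2018,
                       application_year = 2019L,
                       max_age_years = 15L,
                       require_iss = TRUE,
                       unseen_policy = "neutral",
                       min_count = 1L,
                       iciss_variant = "product",
                       thresholds = c(5, 10, 15, 20),
                       threshold_mode = "strict_greater",
                       seed = 1L,
                       n_patients = 20000L,
                       n_codes = 400L,
                       outdir = "pedtriage-run") {
  if (application_year %in% derivation_years)
    abort_invalid("application_year must not be among derivation_years")
  if (max_age_years < 0) abort_invalid("max_age_years must be >= 0")
  if (!threshold_mode %in% c("strict_greater", "geq"))
    abort_invalid("threshold_mode must be 'strict_greater' or 'geq'")
  if (!unseen_policy %in% c("neutral", "cohort_mean", "strict"))
    abort_invalid("unseen_policy must be 'neutral', 'cohort_mean' or 'strict'")
  cfg <- list(derivation_years = as.integer(derivation_years),
              application_year = as.integer(application_year),
              max_age_years = as.integer(max_age_years),
              require_iss = isTRUE(require_iss),
              unseen_policy = unseen_policy,
              min_count = as.integer(min_count),
              iciss_variant = iciss_variant,
              thresholds = as.numeric(thresholds),
              threshold_mode = threshold_mode,
              seed = as.integer(seed),
              n_patients = as.integer(n_patients),
              n_codes = as.integer(n_codes),
              outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' The file may set any subset of the [run_config()] fields; unset fields
#' take their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("the yaml package is required to read YAML configs",
            "pedtriage_io_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort_invalid(paste0("unknown config field(s): ",
                         paste(unknown, collapse = ", ")))
  do.call(run_config, vals)
}

#' Apply the study inclusion criteria
#'
#' Retains patients aged at most `max_age_years`, and (when `require_iss`)
#' those with a non-empty AIS profile, i.e. a computable ISS. Every
#' excluded patient is logged with a reason (`"age"` or `"missing_iss"`;
#' age is checked first).
#'
#' @param cohort Cohort data.frame.
#' @param config A [run_config()].
#' @return List with `included` (cohort subset) and `exclusions`
#'   (data.frame `patient_id,reason`).
#' @export
apply_inclusion <- function(cohort, config) {
  too_old <- cohort$age_years > config$max_age_years
  no_iss <- config$require_iss &
    lengths(cohort$ais_profile) == 0L
  reason <- ifelse(too_old, "age", ifelse(no_iss, "missing_iss", NA))
  drop <- !is.na(reason)
  list(included = cohort[!drop, , drop = FALSE],
       exclusions = data.frame(patient_id = cohort$patient_id[drop],
                               reason = reason[drop],
                               stringsAsFactors = FALSE))
}

#' Run the full derive-apply-classify-evaluate study
#'
#' Orchestrates the whole analysis: simulate (or accept) a registry
#' cohort, apply inclusion criteria, derive SRR/CCRR risk ratios on the
#' derivation years, score the application-year patients (ISS, scaled
#' ICISS, ICASS), classify NFPTCR, and evaluate discrimination (ROC/AUC
#' with DeLong comparisons, the threshold table, and the descriptive group
#' table). All artifacts are written under `config$outdir`:
#' `vocabulary.csv`, `cohort.csv` (when simulated), `exclusions.csv`,
#' `score_table.csv` (+ `.meta.json`), `patient_scores.csv`, `nfptcr.csv`,
#' `table2.csv`, `roc.csv`, `threshold_table.csv`, `auc.json`, and
#' `manifest.json` (config, config MD5, package version, timestamp).
#' Rerunning with an identical config reproduces identical outputs except
#' for the manifest timestamp.
#'
#' @param config A [run_config()].
#' @param cohort Optional user-supplied cohort; when `NULL` one is
#'   simulated from the config's `seed`, `n_patients` and `n_codes` over
#'   `c(derivation_years, application_year)`.
#' @param vocabulary Optional vocabulary accompanying `cohort`.
#' @return Invisibly, a list with the in-memory artifacts (`score_table`,
#'   `scores`, `nfptcr`, `rocs`, `comparisons`, `threshold_table`,
#'   `table2`, `exclusions`, `manifest`).
#' @export
run_study <- function(config, cohort = NULL, vocabulary = NULL) {
  if (!inherits(config, "run_config")) abort_invalid("config must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  simulated <- is.null(cohort)
  if (simulated) {
    vocabulary <- generate_vocabulary(config$n_codes, seed = config$seed)
    spec <- cohort_spec(config$n_patients,
                        years = c(config$derivation_years,
                                  config$application_year),
                        seed = config$seed + 1L)
    cohort <- generate_cohort(spec, vocabulary)
    write_vocabulary_csv(vocabulary, out("vocabulary.csv"))
    write_cohort_csv(cohort, out("cohort.csv"))
  }

  incl <- apply_inclusion(cohort, config)
  utils::write.csv(incl$exclusions, out("exclusions.csv"),
                   row.names = FALSE, quote = FALSE)
  cohort <- incl$included
  deriv <- cohort[cohort$year %in% config$derivation_years, , drop = FALSE]
  appl <- cohort[cohort$year == config$application_year, , drop = FALSE]
  if (nrow(deriv) == 0L) abort_invalid("derivation cohort is empty after inclusion")
  if (nrow(appl) == 0L) abort_invalid("application cohort is empty after inclusion")

  table <- derive_score_table(deriv, min_count = config$min_count)
  write_score_table_csv(table, out("score_table.csv"))

  scores <- apply_scores(appl, table, unseen_policy = config$unseen_policy,
                         variant = config$iciss_variant)
  utils::write.csv(scores, out("patient_scores.csv"), row.names = FALSE,
                   quote = FALSE)

  nf <- classify_nfptcr(appl)
  write_nfptcr_csv(nf, out("nfptcr.csv"))

  labels <- nf$positive
  score_sets <- list(iss = scores$iss, iciss = scores$iciss_scaled,
                     icass = scores$icass)
  rocs <- lapply(names(score_sets), function(m)
    roc_auc(score_sets[[m]], labels, metric_name = m))
  names(rocs) <- names(score_sets)
  roc_points <- do.call(rbind, lapply(rocs, function(r)
    cbind(metric = r$metric_name, r$points)))
  utils::write.csv(roc_points, out("roc.csv"), row.names = FALSE,
                   quote = FALSE)

  pairs <- utils::combn(names(score_sets), 2, simplify = FALSE)
  comparisons <- lapply(pairs, function(p)
    compare_auc(score_sets[[p[1]]], score_sets[[p[2]]], labels,
                metric_a = p[1], metric_b = p[2]))
  auc_json <- list(
    auc = lapply(rocs, function(r)
      list(auc = r$auc, ci_lower = r$auc_ci[1], ci_upper = r$auc_ci[2],
           n_pos = r$n_pos, n_neg = r$n_neg)),
    comparisons = lapply(comparisons, function(cmp)
      list(metric_a = cmp$metric_a, metric_b = cmp$metric_b,
           auc_diff = cmp$auc_diff, statistic = cmp$statistic,
           p_value = cmp$p_value)))
  jsonlite::write_json(auc_json, out("auc.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")

  tt <- threshold_table(score_sets, labels, thresholds = config$thresholds,
                        mode = config$threshold_mode)
  utils::write.csv(tt, out("threshold_table.csv"), row.names = FALSE,
                   quote = FALSE)

  table2 <- describe_cohort(appl, nf, scores)
  utils::write.csv(as.data.frame(table2), out("table2.csv"),
                   row.names = FALSE)

  cfg_path <- out("config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(
                     utils::packageVersion("pedtriage")),
                   r_version = R.version.string,
                   simulated_cohort = simulated,
                   n_input = nrow(incl$included) + nrow(incl$exclusions),
                   n_included = nrow(cohort),
                   n_derivation = nrow(deriv),
                   n_application = nrow(appl),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(score_table = table, scores = scores, nfptcr = nf,
                 rocs = rocs, comparisons = comparisons,
                 threshold_table = tt, table2 = table2,
                 exclusions = incl$exclusions, manifest = manifest))
}
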