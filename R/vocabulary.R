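#' Generate a synthetic diagnosis-code vocabulary
#'
#' Creates a universe of ICD-like diagnosis codes, each carrying the latent
#' quantities the registry analysis later tries to estimate: a survival
#' probability `p_survive` (the estimand of a survival risk ratio) and a
#' critical-care probability `p_critcare` (the estimand of a critical-care
#' risk ratio), plus an AIS body region and severity used to build patient
#' AIS profiles.
#'
#' Each code first receives a latent anatomic severity \eqn{z \sim
#' \mathrm{Beta}(a, b)} and an independent resource-need component
#' \eqn{u} from the same distribution. Mortality rises convexly with
#' anatomic severity, `p_survive = 1 - mortality_scale * z^2 + noise`,
#' while critical-care propensity follows a blend of the two axes,
#' `p_critcare = critcare_scale * (w z + (1-w) u)^critcare_shape + noise`
#' with `w = resource_mix`, both clamped to \[0, 1\]. The blend encodes a
#' structural fact of pediatric trauma that the analysis probes:
#' anatomically graded severity (what AIS/ISS measure) predicts death well
#' but critical-care resource use only partly, because resource need also
#' depends on physiology, age and injury type. Severer codes still kill
#' more *and* use more critical care — `p_critcare` and `1 - p_survive`
#' stay positively coupled — and the defaults keep
#' `p_critcare >= 1 - p_survive` for every code up to noise, which the
#' cohort generator's nested death model relies on (see
#' [generate_cohort()]).
#'
#' Default scales are calibrated to a national pediatric trauma registry's
#' marginals: per-code mortality averaging under 1% and critical-care
#' propensity averaging about 8%, so that a default multi-code cohort shows
#' roughly 1% in-hospital death and a one-in-six critical-care/NFPTCR rate.
#'
#' AIS severity is a noisy monotone discretization of `z` into 1..6 (the
#' noise reflecting the coarseness of AIS coding); probabilities are
#' rounded to 6 decimals so the CSV round-trip is exact.
#'
#' @param n_codes Number of codes to generate (>= 1).
#' @param seed Integer seed; the vocabulary is a pure function of its
#'   arguments.
#' @param severity_shape Length-2 Beta shape parameters for the latent
#'   severity distribution.
#' @param critcare_scale,critcare_shape,critcare_noise_sd Parameters of the
#'   severity-to-critical-care map. `critcare_scale = 0` with zero noise
#'   gives every code `p_critcare = 0`.
#' @param resource_mix Weight `w` of anatomic severity in the critical-care
#'   blend; `1 - w` falls on the independent resource-need component.
#' @param mortality_scale,mortality_noise_sd Parameters of the
#'   severity-to-mortality map. `mortality_scale = 0` with zero noise gives
#'   every code `p_survive = 1`.
#' @param ais_noise_sd Noise of the severity-to-AIS discretization.
#' @param region_weights Sampling weights over the six ISS body regions, in
#'   the order of [body_regions].
#' @return A `data.frame` of class `ped_vocabulary` with columns `code_id`,
#'   `p_survive`, `p_critcare`, `body_region`, `ais_severity`.
#' @examples
#' vocab <- generate_vocabulary(50, seed = 1)
#' cor(vocab$p_critcare, 1 - vocab$p_survive, method = "spearman")
#' @export
generate_vocabulary <- function(n_codes, seed,
                                severity_shape = c(0.7, 2.0),
                                critcare_scale = 0.65,
                                critcare_shape = 2,
                                critcare_noise_sd = 0.03,
                                resource_mix = 0.6,
                                mortality_scale = 0.06,
                                mortality_noise_sd = 0.005,
                                ais_noise_sd = 1.0,
                                region_weights = c(0.22, 0.10, 0.18,
                                                   0.16, 0.24, 0.10)) {
  if (!is.numeric(n_codes) || length(n_codes) != 1L || n_codes < 1)
    abort_invalid("n_codes must be a single integer >= 1")
  n_codes <- as.integer(n_codes)
  stopifnot(length(severity_shape) == 2L, all(severity_shape > 0),
            length(region_weights) == 6L,
            resource_mix >= 0, resource_mix <= 1)

  withr::with_seed(as.integer(seed), {
    z <- stats::rbeta(n_codes, severity_shape[1], severity_shape[2])
    u <- stats::rbeta(n_codes, severity_shape[1], severity_shape[2])
    blend <- resource_mix * z + (1 - resource_mix) * u
    p_critcare <- critcare_scale * blend^critcare_shape +
      stats::rnorm(n_codes, 0, critcare_noise_sd)
    p_survive <- 1 - mortality_scale * z^2 +
      stats::rnorm(n_codes, 0, mortality_noise_sd)
    p_critcare <- round(pmin(1, pmax(0, p_critcare)), 6)
    p_survive <- round(pmin(1, pmax(0, p_survive)), 6)
    ais <- as.integer(pmin(6, pmax(1, round(1 + 5 * z +
                                              stats::rnorm(n_codes, 0,
                                                           ais_noise_sd)))))
    region <- sample(body_regions, n_codes, replace = TRUE,
                     prob = region_weights)
    vocab <- data.frame(
      code_id = sprintf("SYN%04d", seq_len(n_codes)),
      p_survive = p_survive,
      p_critcare = p_critcare,
      body_region = region,
      ais_severity = ais,
      stringsAsFactors = FALSE
    )
    class(vocab) <- c("ped_vocabulary", "data.frame")
    vocab
  })
}

validate_vocabulary <- function(vocab) {
  need <- c("code_id", "p_survive", "p_critcare", "body_region",
            "ais_severity")
  if (!is.data.frame(vocab) || !all(need %in% names(vocab)))
    abort_invalid("vocabulary must have columns code_id, p_survive, p_critcare, body_region, ais_severity")
  if (nrow(vocab) == 0L) abort_invalid("vocabulary is empty")
  if (anyDuplicated(vocab$code_id))
    abort_invalid("vocabulary code_id values must be unique")
  if (any(vocab$p_survive < 0 | vocab$p_survive > 1) ||
      any(vocab$p_critcare < 0 | vocab$p_critcare > 1))
    abort_invalid("p_survive and p_critcare must lie in [0, 1]")
  if (!all(vocab$body_region %in% body_regions))
    abort_invalid("body_region values must be one of the six ISS regions")
  if (!all(vocab$ais_severity %in% 1:6))
    abort_invalid("ais_severity must be an integer in 1..6")
  invisible(vocab)
}

#' Read or write a vocabulary CSV
#'
#' Columns: `code_id,p_survive,p_critcare,body_region,ais_severity`.
#'
#' @param vocab A vocabulary data.frame (see [generate_vocabulary()]).
#' @param path File path.
#' @return `read_vocabulary_csv` returns the validated vocabulary;
#'   `write_vocabulary_csv` returns `path` invisibly.
#' @export
write_vocabulary_csv <- function(vocab, path) {
  validate_vocabulary(vocab)
  utils::write.csv(as.data.frame(vocab), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_vocabulary_csv
#' @export
read_vocabulary_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), "pedtriage_io_error")
  vocab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(code_id = "character",
                                          p_survive = "numeric",
                                          p_critcare = "numeric",
                                          body_region = "character",
                                          ais_severity = "integer"))
  validate_vocabulary(vocab)
  class(vocab) <- c("ped_vocabulary", "data.frame")
  vocab
}
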