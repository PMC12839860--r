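#' Injury Severity Score from an AIS body-region profile
#'
#' Standard AIS-based definition over the six ISS body regions (head/neck,
#' face, chest, abdomen, extremities, external): the sum of squares of the
#' three highest region severities, with any AIS 6 (unsurvivable) injury
#' setting the score to 75. Regions are interchangeable — ties are broken by
#' value only.
#'
#' @param ais_profile Named (or unnamed) integer vector of per-region
#'   maximum AIS severities, values 0-6, 0 = uninjured; regions absent from
#'   the vector count as 0. An empty profile scores 0.
#' @return Integer ISS in 0..75.
#' @examples
#' compute_iss(c(head_neck = 3, chest = 4, extremities = 2))  # 29
#' compute_iss(c(abdomen = 6))                                # 75
#' @export
compute_iss <- function(ais_profile) {
  if (length(ais_profile) == 0L) return(0L)
  sev <- as.integer(ais_profile)
  if (anyNA(sev) || any(sev < 0L | sev > 6L))
    abort_invalid("AIS severities must be integers in 0..6")
  if (length(sev) > length(body_regions))
    abort_invalid("at most six body-region severities allowed")
  if (any(sev == 6L)) return(75L)
  top <- sort(sev, decreasing = TRUE)[1:3]
  top[is.na(top)] <- 0L
  as.integer(sum(top^2))
}
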