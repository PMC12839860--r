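check_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    abort_invalid("scores and labels must have equal length")
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    abort_invalid("scores and labels must not contain missing values")
  if (!any(labels) || all(labels))
    abort("labels must contain at least one positive and one negative",
          "pedtriage_degenerate_labels")
  labels
}

# sample variance, 0 for a single observation (the component is then
# undefined and contributes nothing)
var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)

# midrank placement values: V10 for positives, V01 for negatives
placement_values <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  n_pos <- length(pos)
  n_neg <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(n_pos)] - rank(pos, ties.method = "average")) / n_neg
  v01 <- 1 - (r_all[n_pos + seq_len(n_neg)] -
                rank(neg, ties.method = "average")) / n_pos
  list(v10 = v10, v01 = v01, auc = mean(v10),
       n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted half. Its
#' variance is estimated nonparametrically from the placement values
#' (DeLong), and the 95% CI is formed on the logit scale and
#' back-transformed so it stays inside \[0, 1\]. ROC points enumerate every
#' distinct score value as a cut point (predicted positive = score strictly
#' above the cut), plus a -Inf sentinel.
#'
#' @param scores Numeric score vector (higher = more severe).
#' @param labels Logical (or 0/1) outcome vector; needs at least one
#'   positive and one negative.
#' @param metric_name Optional label carried through to outputs.
#' @param conf_level Confidence level for the AUC interval.
#' @return Object of class `roc_result`: a list with `metric_name`,
#'   `points` (data.frame `threshold,sensitivity,specificity`), `auc`,
#'   `auc_ci`, `auc_se`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.2, 0.6, 0.4, 0.9), c(FALSE, FALSE, TRUE, TRUE))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, metric_name = "score",
                    conf_level = 0.95) {
  labels <- check_labels(scores, labels)
  pv <- placement_values(scores, labels)
  auc <- pv$auc
  v <- var0(pv$v10) / pv$n_pos + var0(pv$v01) / pv$n_neg
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (se == 0) {
    c(auc, auc)
  } else if (auc <= 0 || auc >= 1) {
    pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  } else {
    stats::plogis(stats::qlogis(auc) + c(-1, 1) * z * se / (auc * (1 - auc)))
  }
  thr <- c(-Inf, sort(unique(scores)))
  pos <- scores[labels]
  neg <- scores[!labels]
  points <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg <= t), numeric(1)))
  structure(list(metric_name = metric_name, points = points, auc = auc,
                 auc_ci = ci, auc_se = se, n_pos = pv$n_pos,
                 n_neg = pv$n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC for %s: AUC %.3f (95%% CI %.3f-%.3f), %d+/%d-\n",
              x$metric_name, x$auc, x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same patients against
#' the same outcome. The variance of the AUC difference is estimated from
#' the paired placement-value differences, and the statistic
#' `(AUC_a - AUC_b)^2 / var(diff)` is referred to a chi-square distribution
#' with 1 df (equivalently a two-sided z-test).
#'
#' @param scores_a,scores_b Numeric score vectors on the same patients.
#' @param labels Shared outcome labels.
#' @param metric_a,metric_b Optional labels.
#' @return Object of class `auc_comparison`: list with `metric_a`,
#'   `metric_b`, `auc_a`, `auc_b`, `auc_diff`, `statistic`, `p_value`.
#'   When the variance of the difference is zero and the AUCs are equal
#'   (e.g. a score compared to a monotone transform of itself) the
#'   statistic is `NA` and the p-value 1.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        metric_a = "a", metric_b = "b") {
  labels <- check_labels(scores_a, labels)
  check_labels(scores_b, labels)
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  diff <- pa$auc - pb$auc
  v <- var0(pa$v10 - pb$v10) / pa$n_pos +
    var0(pa$v01 - pb$v01) / pa$n_neg
  if (v <= 0) {
    stat <- NA_real_
    p <- if (abs(diff) < .Machine$double.eps^0.5) 1 else 0
  } else {
    stat <- diff^2 / v
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(metric_a = metric_a, metric_b = metric_b,
                 auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff,
                 var_diff = max(v, 0), statistic = stat, p_value = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %s %.3f vs %s %.3f: diff %+.3f, chi-sq(1) %s, p %.3g\n",
              x$metric_a, x$auc_a, x$metric_b, x$auc_b, x$auc_diff,
              ifelse(is.na(x$statistic), "NA", sprintf("%.2f", x$statistic)),
              x$p_value))
  invisible(x)
}

#' Sensitivity and specificity at a fixed threshold
#'
#' @inheritParams roc_auc
#' @param threshold Cut point.
#' @param mode `"strict_greater"` (default; predicted positive iff score >
#'   threshold, matching threshold labels like "score > 5") or `"geq"`
#'   (score >= threshold).
#' @return One-row `data.frame` `metric,threshold,sensitivity,specificity`
#'   with sensitivity and specificity as percentages.
#' @export
sens_spec_at <- function(scores, labels, threshold,
                         mode = c("strict_greater", "geq"),
                         metric_name = "score") {
  mode <- match.arg(mode)
  labels <- check_labels(scores, labels)
  pred <- if (mode == "strict_greater") scores > threshold else
    scores >= threshold
  data.frame(metric = metric_name, threshold = threshold,
             sensitivity = 100 * sum(pred & labels) / sum(labels),
             specificity = 100 * sum(!pred & !labels) / sum(!labels),
             stringsAsFactors = FALSE)
}

#' Threshold sensitivity/specificity table for several metrics
#'
#' Assembles, for each named score vector, sensitivity and specificity at
#' each threshold plus the metric's AUC — the standard operating-
#' characteristics table for comparing severity scores against a binary
#' resource-need outcome.
#'
#' @param score_sets Named list of numeric score vectors on the same
#'   patients.
#' @param labels Shared outcome labels.
#' @param thresholds Numeric thresholds (default `c(5, 10, 15, 20)`).
#' @param mode Threshold convention, see [sens_spec_at()].
#' @return `data.frame` with columns
#'   `metric,threshold,sensitivity,specificity,auc` (one row per metric x
#'   threshold; empty if `thresholds` is empty).
#' @export
threshold_table <- function(score_sets, labels,
                            thresholds = c(5, 10, 15, 20),
                            mode = c("strict_greater", "geq")) {
  mode <- match.arg(mode)
  stopifnot(is.list(score_sets), !is.null(names(score_sets)))
  rows <- list()
  for (m in names(score_sets)) {
    auc <- roc_auc(score_sets[[m]], labels, metric_name = m)$auc
    for (t in thresholds) {
      r <- sens_spec_at(score_sets[[m]], labels, t, mode, metric_name = m)
      r$auc <- auc
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L)
    return(data.frame(metric = character(0), threshold = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0),
                      auc = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
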