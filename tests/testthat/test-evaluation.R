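test_that("AUC handles the canonical edge cases", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(T, F, T, F, F, T))$auc, 0.5)
  expect_equal(roc_auc(c(0.2, 0.6, 0.4, 0.9), c(F, F, T, T))$auc, 0.75)
  expect_error(roc_auc(1:4, c(T, T, T, T)),
               class = "pedtriage_degenerate_labels")
  expect_error(roc_auc(1:3, c(T, F)), class = "pedtriage_invalid_argument")
})

test_that("AUC matches brute-force pair counting on random fixtures", {
  withr::with_seed(101, {
    for (i in 1:40) {
      n <- sample(4:50, 1)
      scores <- sample(0:20, n, replace = TRUE)  # ties likely
      labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels))
    }
  })
})

test_that("AUC agrees with an independent DeLong implementation", {
  withr::with_seed(7, {
    scores <- rnorm(200) + rep(c(0, 1), each = 100)
    labels <- rep(c(FALSE, TRUE), each = 100)
  })
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  # same DeLong variance; our interval is logit-transformed, so compare se
  expect_equal(ours$auc_se, (ref_ci[3] - ref_ci[1]) / (2 * qnorm(0.975)),
               tolerance = 1e-6)
  expect_true(ours$auc_ci[1] <= ours$auc & ours$auc <= ours$auc_ci[2])
})

test_that("ROC points are monotone and AUC flips under label inversion", {
  withr::with_seed(23, {
    scores <- round(runif(80, 0, 30), 1)
    labels <- runif(80) < plogis(scores / 8 - 1.5)
    labels[1:2] <- c(TRUE, FALSE)
  })
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$points$sensitivity) <= 0))
  expect_true(all(diff(r$points$specificity) >= 0))
  expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc)
  expect_equal(roc_auc(scores, !labels)$auc, 1 - r$auc)
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(29, {
    scores <- rgamma(60, 2)
    labels <- runif(60) < plogis(scores - 2)
    labels[1:2] <- c(TRUE, FALSE)
  })
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(log1p(scores), labels)$auc, a)
  expect_equal(roc_auc(100 * scores + 3, labels)$auc, a)
  cmp <- compare_auc(scores, log1p(scores), labels)
  expect_equal(cmp$auc_diff, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("a score compared with itself yields no difference", {
  cmp <- compare_auc(c(1, 3, 2, 4), c(1, 3, 2, 4), c(F, F, T, T))
  expect_equal(cmp$auc_diff, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(is.na(cmp$statistic))
})

test_that("the paired DeLong test agrees with pROC and a bootstrap oracle", {
  withr::with_seed(37, {
    n <- 12
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    a <- rnorm(n, mean = ifelse(labels, 1, 0))
    b <- 0.5 * a + rnorm(n, mean = ifelse(labels, 0.3, 0))
  })
  cmp <- compare_auc(a, b, labels)

  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  # pROC reports a z statistic; ours is its square (chi-square, 1 df)
  expect_equal(cmp$statistic, unname(ref$statistic)^2, tolerance = 1e-8)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-8)

  # stratified paired bootstrap estimate of var(AUC_a - AUC_b)
  withr::with_seed(41, {
    diffs <- replicate(10000, {
      ip <- sample(which(labels), replace = TRUE)
      ineg <- sample(which(!labels), replace = TRUE)
      idx <- c(ip, ineg)
      lab <- labels[idx]
      pair_count_auc(a[idx], lab) - pair_count_auc(b[idx], lab)
    })
  })
  expect_lt(abs(var(diffs) - cmp$var_diff) / cmp$var_diff, 0.2)
})

test_that("sensitivity and specificity follow the confusion matrix", {
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  labels <- c(F, F, F, F, F, F, T, T, T, T)
  # hand count at threshold 6, strict: TP 4 FN 0, TN 6 FP 0
  row <- sens_spec_at(scores, labels, 6)
  expect_equal(row$sensitivity, 100)
  expect_equal(row$specificity, 100)
  # at threshold 7: positive iff score > 7 -> TP 3 FN 1
  row <- sens_spec_at(scores, labels, 7)
  expect_equal(row$sensitivity, 75)
  expect_equal(row$specificity, 100)
  # geq mode includes the boundary
  row <- sens_spec_at(scores, labels, 7, mode = "geq")
  expect_equal(row$sensitivity, 100)
  # threshold below all scores
  row <- sens_spec_at(scores, labels, 0)
  expect_equal(row$sensitivity, 100)
  expect_equal(row$specificity, 0)
})

test_that("threshold table composes per-metric rows with an AUC column", {
  withr::with_seed(53, {
    labels <- runif(300) < 0.3
    labels[1:2] <- c(TRUE, FALSE)
    sets <- list(iss = rpois(300, 8) + 4 * labels,
                 icass = runif(300, 0, 40) + 15 * labels,
                 iciss = runif(300, 0, 30) + 10 * labels)
  })
  tt <- threshold_table(sets, labels)
  expect_equal(nrow(tt), 12L)
  expect_identical(names(tt), c("metric", "threshold", "sensitivity",
                                "specificity", "auc"))
  for (m in names(sets)) {
    sub <- tt[tt$metric == m, ]
    expect_true(all(diff(sub$sensitivity) <= 0))
    expect_true(all(diff(sub$specificity) >= 0))
    expect_equal(unique(sub$auc), roc_auc(sets[[m]], labels)$auc)
    r5 <- sens_spec_at(sets[[m]], labels, 5, metric_name = m)
    expect_equal(sub$sensitivity[sub$threshold == 5], r5$sensitivity)
  }
  expect_equal(nrow(threshold_table(sets, labels, thresholds = numeric(0))),
               0L)
})

test_that("group descriptives use chi-square and rank tests correctly", {
  # 2x2 table [[10,10],[10,10]]: no association, statistic 0, p 1
  co <- do.call(bind_records, lapply(1:40, function(i)
    patient_record(sprintf("p%02d", i), sex = c("M", "F")[1 + i %% 2],
                   age_years = 7L, abuse_flag = i <= 20)))
  nf <- classify_nfptcr(co)
  sm <- describe_cohort(co, nf)
  sex_rows <- sm[sm$variable == "sex", ]
  expect_equal(unique(sex_rows$statistic), 0)
  expect_equal(unique(sex_rows$p_value), 1)

  # ages {4,5,6} vs {1,2,3}: Kruskal-Wallis H = 3.857 (no ties, k = 2)
  co6 <- do.call(bind_records, lapply(1:6, function(i)
    patient_record(sprintf("q%d", i), age_years = i,
                   abuse_flag = i >= 4)))
  sm6 <- describe_cohort(co6, classify_nfptcr(co6))
  h <- sm6$statistic[sm6$variable == "age_years"]
  expect_equal(h, 12 / (6 * 7) * (3 * (5 - 3.5)^2 + 3 * (2 - 3.5)^2),
               tolerance = 1e-6)
  expect_equal(h, 3.857, tolerance = 1e-3)

  # degenerate group
  allpos <- do.call(bind_records, lapply(1:4, function(i)
    patient_record(sprintf("r%d", i), abuse_flag = TRUE)))
  expect_error(describe_cohort(allpos, classify_nfptcr(allpos)),
               class = "pedtriage_degenerate_group")
})
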