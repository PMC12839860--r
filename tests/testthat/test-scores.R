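# enumeration oracle for ISS: max over all 3-subsets of region severities,
# independent of the implementation's sort-based shortcut
iss_oracle <- function(sev) {
  sev <- c(sev, integer(max(0, 3 - length(sev))))
  if (any(sev == 6)) return(75L)
  best <- 0L
  for (s in utils::combn(seq_along(sev), 3, simplify = FALSE))
    best <- max(best, sum(sev[s]^2))
  as.integer(best)
}

test_that("ISS follows the AIS sum-of-squares rule", {
  expect_identical(compute_iss(c(head_neck = 3, chest = 4, extremities = 2)),
                   29L)
  expect_identical(compute_iss(full_profile(abdomen = 6, face = 1)), 75L)
  expect_identical(compute_iss(c(5, 4, 3, 2)), iss_oracle(c(5, 4, 3, 2)))
  expect_identical(compute_iss(c(5, 4, 3, 2)), 50L)
  expect_identical(compute_iss(integer(0)), 0L)
  expect_identical(compute_iss(c(2)), 4L)
  expect_error(compute_iss(c(head_neck = 7)),
               class = "pedtriage_invalid_argument")
})

test_that("ISS matches the subset-enumeration oracle on random profiles", {
  withr::with_seed(42, {
    for (i in 1:100) {
      sev <- sample(0:6, sample(1:6, 1), replace = TRUE)
      expect_identical(compute_iss(sev), iss_oracle(sev))
    }
  })
})

test_that("risk ratios follow their defining tallies", {
  co <- planted_cohort(list(A = c(10L, 6L), B = c(10L, 0L, 0L)))
  tab <- derive_score_table(co)
  expect_equal(tab$ccrr[tab$code_id == "A"], 60)
  expect_equal(tab$srr[tab$code_id == "B"], 1)
  expect_equal(tab$n_patients, c(10L, 10L))
})

test_that("duplicate codes within one patient count once", {
  rec <- patient_record(codes = c("A", "A", "B"), icu_days = 3L)
  tab <- derive_score_table(rec)
  expect_equal(tab$n_patients, c(1L, 1L))
  expect_equal(score_icass(rec, tab), 100)
})

test_that("score table matches a naive per-code recount on small cohorts", {
  naive_recount <- function(cohort) {
    cc <- default_critcare_rule(cohort)
    all_codes <- sort(unique(unlist(cohort$codes)))
    do.call(rbind, lapply(all_codes, function(code) {
      carriers <- vapply(cohort$codes, function(cs) code %in% cs, logical(1))
      data.frame(code_id = code, n_patients = sum(carriers),
                 n_survivors = sum(carriers & !cohort$died),
                 n_critcare = sum(carriers & cc),
                 stringsAsFactors = FALSE)
    }))
  }
  vocab <- generate_vocabulary(15, seed = 21)
  for (seed in 1:5) {
    co <- generate_cohort(cohort_spec(sample(20:100, 1), seed = seed), vocab)
    tab <- derive_score_table(co)
    ref <- naive_recount(co)
    expect_equal(tab$n_patients, ref$n_patients)
    expect_equal(tab$n_survivors, ref$n_survivors)
    expect_equal(tab$n_critcare, ref$n_critcare)
    expect_equal(tab$srr, ref$n_survivors / ref$n_patients)
    expect_equal(tab$ccrr, 100 * ref$n_critcare / ref$n_patients)
  }
})

test_that("min_count drops rare codes from the table", {
  co <- planted_cohort(list(A = c(10L, 2L), B = c(2L, 1L)))
  tab <- derive_score_table(co, min_count = 3L)
  expect_identical(tab$code_id, "A")
  expect_error(derive_score_table(co[0, ]),
               class = "pedtriage_invalid_argument")
})

make_table <- function(ids, srr, ccrr) {
  data.frame(code_id = ids, n_patients = 10L,
             n_survivors = as.integer(round(10 * srr)),
             n_critcare = as.integer(round(ccrr / 10)),
             srr = srr, ccrr = ccrr, stringsAsFactors = FALSE)
}

test_that("ICISS is the inverted SRR product on the 0-100 scale", {
  tab <- make_table(c("A", "B", "C"), c(0.9, 0.8, 1), c(0, 0, 0))
  expect_equal(score_iciss("A", tab), 10)
  expect_equal(score_iciss(c("A", "B"), tab), 28)
  expect_equal(score_iciss("C", tab), 0)
  expect_equal(score_iciss(c("A", "B"), tab, variant = "worst"), 20)
})

test_that("ICASS is the maximum CCRR over the patient's codes", {
  tab <- make_table(c("A", "B", "C", "D"), c(1, 1, 1, 1),
                    c(45, 60, 12.5, 0))
  expect_equal(score_icass(c("A", "B"), tab), 60)
  expect_equal(score_icass("D", tab), 0)
  expect_equal(score_icass(c("C", "C", "D"), tab), 12.5)
})

test_that("unseen-code policies behave as documented", {
  tab <- make_table(c("A", "B"), c(0.9, 0.7), c(40, 20))
  expect_equal(score_iciss(c("A", "ZZZ"), tab, "neutral"), 10)
  expect_equal(score_icass(c("D", "ZZZ"), tab, "neutral"), 0)
  expect_equal(score_icass("ZZZ", tab, "cohort_mean"), 30)
  expect_equal(score_iciss("ZZZ", tab, "cohort_mean"), 20)
  expect_equal(score_iciss(c("A", "ZZZ"), tab, "strict"), 10)
  expect_error(score_icass("ZZZ", tab, "strict"),
               class = "pedtriage_unresolvable_score")
  expect_error(score_icass("A", tab, "nonsense"),
               class = "pedtriage_invalid_argument")
})

test_that("adding codes never decreases severity scores", {
  withr::with_seed(31, {
    tab <- make_table(sprintf("C%02d", 1:20), round(runif(20, 0.5, 1), 3),
                      round(runif(20, 0, 80), 1))
    for (i in 1:50) {
      base <- sample(tab$code_id, sample(1:4, 1))
      extra <- sample(setdiff(tab$code_id, base), 1)
      expect_gte(score_icass(c(base, extra), tab),
                 score_icass(base, tab))
      if (tab$srr[tab$code_id == extra] < 1)
        expect_gte(score_iciss(c(base, extra), tab),
                   score_iciss(base, tab))
    }
  })
})

test_that("scores stay within their declared 0-100 ranges", {
  vocab <- generate_vocabulary(50, seed = 17)
  co <- generate_cohort(cohort_spec(400, seed = 18), vocab)
  tab <- derive_score_table(co)
  sc <- suppressWarnings(apply_scores(co, tab))  # same-cohort scoring intended
  expect_true(all(sc$iss >= 0 & sc$iss <= 75))
  expect_true(all(sc$iciss_scaled >= 0 & sc$iciss_scaled <= 100))
  expect_true(all(sc$icass >= 0 & sc$icass <= 100))
  # ISS is 75 or a sum of three squares of 0..5
  sums3 <- unique(c(apply(expand.grid(0:5, 0:5, 0:5)^2, 1, sum), 75L))
  expect_true(all(sc$iss %in% sums3))
})

test_that("apply_scores preserves order, handles empties, names failing patients", {
  tab <- make_table(c("A", "B"), c(0.9, 0.8), c(45, 60))
  expect_equal(nrow(apply_scores(patient_record()[0, ], tab)), 0L)

  co <- bind_records(
    patient_record("p2", codes = "B", year = 2019L),
    patient_record("p1", codes = c("A", "B"), year = 2019L))
  sc <- apply_scores(co, tab)
  expect_identical(sc$patient_id, c("p2", "p1"))
  expect_equal(sc$icass, c(60, 60))

  co$codes[[2]] <- "UNSEEN"
  expect_error(apply_scores(co, tab, unseen_policy = "strict"), "p1",
               class = "pedtriage_unresolvable_score")
})

test_that("scoring a cohort that overlaps the derivation years warns", {
  co <- planted_cohort(list(A = c(5L, 2L)), year = 2018L)
  tab <- derive_score_table(co)
  expect_warning(apply_scores(co, tab), "derivation")
})

test_that("score tables round-trip through CSV with metadata", {
  co <- planted_cohort(list(A = c(10L, 6L), B = c(8L, 3L, 1L)))
  tab <- derive_score_table(co, min_count = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table_csv(tab, path)
  back <- read_score_table_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(attr(back, "years"), attr(tab, "years"))
  expect_identical(attr(back, "min_count"), 2L)
})
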