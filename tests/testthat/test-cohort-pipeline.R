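test_that("inclusion/exclusion applies the documented rules in order", {
  res <- apply_inclusion_exclusion(toy_cohort())
  # age 16 excluded (strict 'over 16'), age 17 retained,
  # re-admission record (P2 index 2) removed
  expect_equal(res$report$step,
               c("age_over_16", "typeb_dissection_repair",
                 "icu_before_surgery", "first_admission_only"))
  expect_equal(res$report$n_excluded, c(1, 0, 0, 1))
  expect_equal(nrow(res$cohort), 4)
  expect_false(16 %in% res$cohort$age)
  expect_true(17 %in% res$cohort$age)
  expect_false(any(res$cohort$readmission_index > 1))
  # conservation at every step
  expect_equal(res$report$n_in, res$report$n_excluded + res$report$n_out)
})

test_that("empty cohort passes through the filters with zero counts", {
  empty <- toy_cohort()[0, ]
  res <- apply_inclusion_exclusion(empty)
  expect_equal(nrow(res$cohort), 0)
  expect_true(all(res$report$n_in == 0))
  res2 <- month_completeness_filter(empty)
  expect_equal(res2$report$n_excluded, 0)
})

test_that("missing required columns are named in the error", {
  bad <- toy_cohort(); bad$age <- NULL
  expect_error(apply_inclusion_exclusion(bad), "age")
})

test_that("month completeness rule removes whole strata above 10% only", {
  mk <- function(n, n_incomplete, month, center = "C01") {
    data.frame(center_id = center, admission_month = month,
               complete = rep(c(FALSE, TRUE), c(n_incomplete, n - n_incomplete)))
  }
  # 20% incomplete: all 10 removed (including the 8 complete ones);
  # exactly 10%: retained (strict inequality)
  cohort <- rbind(mk(10, 2, "2016-01"), mk(10, 1, "2016-02"))
  res <- month_completeness_filter(cohort)
  expect_equal(res$report$n_excluded, 10)
  expect_true(all(res$cohort$admission_month == "2016-02"))

  all_complete <- mk(10, 0, "2016-03")
  expect_equal(nrow(month_completeness_filter(all_complete)$cohort), 10)

  # strata are per (center, month): another center's clean month survives
  two_centers <- rbind(mk(10, 5, "2016-01", "C01"),
                       mk(10, 0, "2016-01", "C02"))
  res2 <- month_completeness_filter(two_centers)
  expect_equal(unique(res2$cohort$center_id), "C02")
})

test_that("filters are idempotent", {
  g <- generate_cohort(synthetic_config(n_centers = 3,
                                        patients_per_center = 300,
                                        seed = 11))
  once <- month_completeness_filter(apply_inclusion_exclusion(g$cohort)$cohort)
  twice <- month_completeness_filter(once$cohort)
  expect_equal(twice$cohort, once$cohort)
  expect_equal(twice$report$n_excluded, 0)
  m1 <- exclude_missing_outcome(once$cohort)
  m2 <- exclude_missing_outcome(m1$cohort)
  expect_equal(m2$cohort, m1$cohort)
})

test_that("missing-outcome exclusion matches its generating rate", {
  res <- exclude_missing_outcome(toy_cohort())
  expect_equal(res$report$n_excluded, 1)
  expect_false(any(res$cohort$hospital_outcome == "missing"))

  cfg <- synthetic_config(n_centers = 10, patients_per_center = 1000,
                          seed = 21, readmission_rate = 0,
                          incomplete_month_rate = 0,
                          missing_outcome_rate = 0.02)
  g <- generate_cohort(cfg)
  excl <- exclude_missing_outcome(g$cohort)$report$n_excluded
  n <- nrow(g$cohort)
  se <- sqrt(n * 0.02 * 0.98)
  expect_lt(abs(excl - n * 0.02), 3 * se)
})

test_that("train/validation split has exact sizes and is reproducible", {
  cohort <- data.frame(row_id = 1:100)
  sp <- split_train_validation(cohort, 0.85, seed = 4)
  expect_length(sp$train_ids, 85)
  expect_length(sp$validation_ids, 15)
  expect_length(intersect(sp$train_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$train_ids, sp$validation_ids), 1:100)
  sp2 <- split_train_validation(cohort, 0.85, seed = 4)
  expect_identical(sp, sp2)

  # round-half-even arithmetic at the study's scale
  big <- data.frame(row_id = seq_len(15533))
  spb <- split_train_validation(big, 0.85, seed = 1)
  expect_length(spb$train_ids, 13203)
  expect_length(spb$validation_ids, 2330)

  expect_error(split_train_validation(big, 1.2), "fraction")
  expect_error(split_train_validation(big[1, , drop = FALSE]), "at least 2")
})

test_that("flowchart report chains counts and flags breaches", {
  r1 <- dualbench:::new_filter_report("a", 10, 2)
  r2 <- dualbench:::new_filter_report("b", 8, 0)
  r3 <- dualbench:::new_filter_report("c", 8, 1)
  tab <- flowchart_report(list(r1, r2, r3))
  expect_equal(tab$n_out, c(8, 8, 7))
  bad <- dualbench:::new_filter_report("b", 9, 0)
  expect_error(flowchart_report(list(r1, bad)), "conservation")
})
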