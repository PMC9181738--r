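test_that("expected deaths is the sum of probabilities", {
  expect_equal(expected_deaths(c(0.1, 0.2, 0.3)), 0.6)
  expect_equal(expected_deaths(numeric(0)), 0)
  expect_error(expected_deaths(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("relative difference is the exact ratio with a guarded domain", {
  expect_equal(relative_difference(10, 10), 0)
  expect_equal(relative_difference(0.10, 0.12), 0.2)
  expect_error(relative_difference(0, 1), "undefined")
})

test_that("identical pre/post models give d = 0 with a zero-width CI", {
  g <- generate_cohort(quick_config(n_centers = 1, npc = 400, seed = 17))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  m <- fit_risk_model(cohort, list(term_linear("age")), "pre")
  m_post <- m; m_post$stage <- "post"
  bm <- benchmark_centers(cohort, m, m_post, subgroups = NULL, B = 50,
                          seed = 1)
  expect_equal(bm$d, 0, tolerance = 1e-12)
  expect_equal(bm$ci_low, 0, tolerance = 1e-10)
  expect_equal(bm$ci_high, 0, tolerance = 1e-10)
})

test_that("unit expected deaths are additive over subgroup partitions", {
  g <- generate_cohort(quick_config(n_centers = 3, npc = 500, seed = 19,
                                    shifts = c(-0.3, 0, 0.3)))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  pre_terms <- list(age = term_piecewise("age", 60),
                    clearance = term_linear("creatinine_clearance"))
  post_terms <- c(pre_terms, list(term_linear("icu_lactate"),
                                  term_linear("icu_severity")))
  pre <- fit_risk_model(cohort, pre_terms, "pre")
  post <- fit_risk_model(cohort, post_terms, "post")
  parts <- list(elective = function(d) d$urgency == "elective",
                non_elective = function(d) d$urgency != "elective")
  bm <- benchmark_centers(cohort, pre, post, subgroups = parts, B = 10,
                          seed = 1)
  for (cc in unique(bm$center_id)) {
    sub <- bm[bm$center_id == cc, ]
    expect_equal(sub$e_pre[sub$subgroup == "overall"],
                 sum(sub$e_pre[sub$subgroup != "overall"]),
                 tolerance = 1e-9)
    expect_equal(sub$e_post[sub$subgroup == "overall"],
                 sum(sub$e_post[sub$subgroup != "overall"]),
                 tolerance = 1e-9)
  }
  # sign coherence across all units
  expect_equal(bm$d > 0, bm$e_post > bm$e_pre)
})

test_that("bootstrap confidence intervals are seed-deterministic", {
  g <- generate_cohort(quick_config(n_centers = 2, npc = 400, seed = 23,
                                    shifts = c(0, 0.3)))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  pre <- fit_risk_model(cohort, validation_study_terms("pre"), "pre")
  post <- fit_risk_model(cohort, validation_study_terms("post"), "post")
  b1 <- benchmark_centers(cohort, pre, post, subgroups = NULL, B = 100,
                          seed = 11)
  b2 <- benchmark_centers(cohort, pre, post, subgroups = NULL, B = 100,
                          seed = 11)
  b3 <- benchmark_centers(cohort, pre, post, subgroups = NULL, B = 100,
                          seed = 12)
  expect_identical(b1, b2)
  expect_false(identical(b1$ci_low, b3$ci_low))

  # stratified resampling is also reproducible and keeps unit sizes
  s1 <- benchmark_centers(cohort, pre, post, subgroups = NULL, B = 50,
                          seed = 5, stratified = TRUE)
  s2 <- benchmark_centers(cohort, pre, post, subgroups = NULL, B = 50,
                          seed = 5, stratified = TRUE)
  expect_identical(s1, s2)
})

test_that("empty units are omitted with a warning", {
  g <- generate_cohort(quick_config(n_centers = 2, npc = 300, seed = 29))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  cohort$mvr <- FALSE  # no MVR patients anywhere
  pre <- fit_risk_model(cohort, list(term_linear("age")), "pre")
  post <- fit_risk_model(cohort, list(term_linear("age"),
                                      term_linear("icu_lactate")), "post")
  expect_warning(
    bm <- benchmark_centers(cohort, pre, post,
                            subgroups = list(MVR = function(d) d$mvr),
                            B = 10, seed = 1),
    "empty unit")
  expect_false(any(bm$subgroup == "MVR"))
})

test_that("forest export sorts ascending in d", {
  bm <- structure(data.frame(
    unit = c("C01", "C02", "C03"), center_id = c("C01", "C02", "C03"),
    subgroup = "overall", n = c(10, 20, 30),
    e_pre = c(1, 2, 3), e_post = c(1.3, 1.6, 2.4),
    d = c(0.3, -0.2, -0.2 + 1e-9), ci_low = NA, ci_high = NA,
    B = 10, n_usable = 10), class = c("center_benchmark", "data.frame"))
  f <- export_forest(bm)
  expect_equal(f$unit, c("C02", "C03", "C01"))
  expect_warning(export_forest(bm, subgroup = "CABG"), "no units")
})
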