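test_that("same config and seed give identical cohort and truth", {
  cfg <- synthetic_config(n_centers = 3, patients_per_center = 150, seed = 42)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$true_values$patients, g2$true_values$patients)
  g3 <- generate_cohort(synthetic_config(n_centers = 3,
                                         patients_per_center = 150,
                                         seed = 43))
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("zero shifts and zero intraoperative noise give true d = 0", {
  cfg <- quick_config(n_centers = 4, npc = 200, sd = 0,
                      shifts = rep(0, 4))
  g <- generate_cohort(cfg)
  expect_true(all(g$true_values$centers$d == 0))
  expect_identical(g$true_values$patients$p_pre,
                   g$true_values$patients$p_post)
})

test_that("intercept-only generator reproduces its Bernoulli rate", {
  cfg <- quick_config(n_centers = 20, npc = 1000, sd = 0, seed = 7,
                      shifts = rep(0, 20),
                      preop_coefficients = intercept_only_coefs(qlogis(0.05)))
  g <- generate_cohort(cfg)
  n <- nrow(g$cohort)
  expect_equal(n, 20000)
  obs <- mean(g$cohort$hospital_outcome == "dead")
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(obs - 0.05), 3 * se)
  expect_true(all(abs(g$true_values$patients$p_pre - 0.05) < 1e-12))
})

test_that("raising one center's shift raises only that center's true d", {
  base <- quick_config(n_centers = 3, npc = 300, seed = 5,
                       shifts = c(0, 0, 0))
  up <- quick_config(n_centers = 3, npc = 300, seed = 5,
                     shifts = c(0, 0.4, 0))
  g0 <- generate_cohort(base)
  g1 <- generate_cohort(up)
  expect_gt(true_center_d(g1$true_values, "C02"),
            true_center_d(g0$true_values, "C02"))
  expect_equal(true_center_d(g1$true_values, "C01"),
               true_center_d(g0$true_values, "C01"))
  expect_equal(true_center_d(g1$true_values, "C03"),
               true_center_d(g0$true_values, "C03"))
})

test_that("observed center deaths agree with true expected deaths", {
  # generator calibration: over 100 seeds, per-center observed deaths fall
  # within 3 binomial standard errors of true e_post nearly always
  hits <- 0; total <- 0
  for (s in 1:100) {
    cfg <- quick_config(n_centers = 3, npc = 1000, seed = s,
                        shifts = c(-0.2, 0, 0.3))
    g <- generate_cohort(cfg)
    for (cc in unique(g$cohort$center_id)) {
      sel <- g$cohort$center_id == cc
      obs <- sum(g$cohort$hospital_outcome[sel] == "dead")
      tv <- g$true_values
      psel <- tv$patients$center_id == cc
      e <- sum(tv$patients$p_post[psel])
      se <- sqrt(sum(tv$patients$p_post[psel] *
                       (1 - tv$patients$p_post[psel])))
      total <- total + 1
      if (abs(obs - e) <= 3 * se) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("true_center_d is the exact ratio of true expected deaths", {
  # formula check on a constructed single-patient center
  tv <- structure(list(centers = data.frame(
    center_id = "C01", n = 1, e_pre = 0.10, e_post = 0.12, d = 0.2)),
    class = "true_values")
  expect_equal(true_center_d(tv, "C01"), 0.2)

  # summation oracle on a heterogeneous case-mix with a +0.5 shift
  cfg <- quick_config(n_centers = 2, npc = 500, seed = 9,
                      shifts = c(0.5, 0), sd = 0)
  g <- generate_cohort(cfg)
  pat <- g$true_values$patients
  sel <- pat$center_id == "C01"
  d_oracle <- (sum(pat$p_post[sel]) - sum(pat$p_pre[sel])) /
    sum(pat$p_pre[sel])
  expect_equal(true_center_d(g$true_values, "C01"), d_oracle)
  expect_gt(d_oracle, 0)

  expect_error(true_center_d(g$true_values, "C99"), "not present")
})

test_that("invalid config fields are rejected by name", {
  expect_error(synthetic_config(readmission_rate = 1.5),
               "readmission_rate")
  expect_error(synthetic_config(n_centers = 0), "n_centers")
  expect_error(synthetic_config(postop_noise_sd = -1), "postop_noise_sd")
  co <- default_preop_coefficients()
  co$age$knots <- c(70, 60); co$age$slopes <- c(0, 0, 0)
  expect_error(synthetic_config(preop_coefficients = co), "knots")
  expect_error(
    synthetic_config(n_centers = 3, center_intraop_shift = c(0, 0)),
    "center_intraop_shift")
})

test_that("cohort CSV round trip preserves the table", {
  g <- generate_cohort(synthetic_config(n_centers = 2,
                                        patients_per_center = 80,
                                        seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(g$cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back$patient_id, g$cohort$patient_id)
  expect_equal(back$complete, g$cohort$complete)
  expect_equal(back$creatinine_clearance, g$cohort$creatinine_clearance,
               tolerance = 1e-12)
})
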