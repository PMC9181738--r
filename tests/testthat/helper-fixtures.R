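# Small cohorts built in code, shared across test files.

# Minimal hand-built cohort for the filter tests.
toy_cohort <- function() {
  data.frame(
    row_id = 1:6,
    patient_id = c("P1", "P2", "P2", "P3", "P4", "P5"),
    center_id = "C01",
    admission_month = "2016-01",
    admission_ts = sprintf("2016-01-%02d", 1:6),
    readmission_index = c(1L, 1L, 2L, 1L, 1L, 1L),
    age = c(70, 55, 55, 17, 16, 80),
    complete = TRUE,
    icu_before_surgery = FALSE,
    typeb_dissection_repair = FALSE,
    hospital_outcome = c("alive", "alive", "alive", "dead", "alive", "missing"),
    stringsAsFactors = FALSE
  )
}

# Cohort of binary exposure / outcome counts (for closed-form oracles):
# a deaths and b survivors among exposed, c deaths and d survivors among
# unexposed.
counts_cohort <- function(a, b, c, d) {
  data.frame(
    exposure = rep(c(TRUE, FALSE), c(a + b, c + d)),
    hospital_outcome = c(rep(c("dead", "alive"), c(a, b)),
                         rep(c("dead", "alive"), c(c, d))),
    stringsAsFactors = FALSE
  )
}

# Small clean synthetic config (no registry messiness).
quick_config <- function(n_centers = 3, npc = 400, seed = 1,
                         shifts = rep(0, n_centers), sd = 0.5, ...) {
  synthetic_config(
    n_centers = n_centers, patients_per_center = npc, seed = seed,
    center_intraop_shift = shifts, postop_noise_sd = sd,
    readmission_rate = 0, incomplete_month_rate = 0,
    missing_outcome_rate = 0, pediatric_rate = 0,
    icu_before_surgery_rate = 0, typeb_rate = 0, ...)
}

# Intercept-only generating process: every covariate effect zero.
intercept_only_coefs <- function(intercept) {
  co <- default_preop_coefficients()
  co$intercept <- intercept
  co$age <- list(knots = numeric(0), slopes = 0)
  co$creatinine_clearance <- list(knots = numeric(0), slopes = 0)
  co$sex[] <- 0; co$nyha[] <- 0; co$ef_class[] <- 0; co$urgency[] <- 0
  co$redo <- 0; co$avs <- 0; co$mvp <- 0; co$mvr <- 0; co$cabg <- 0
  co$aa <- 0
  co
}

# two-sided binomial acceptance band at alpha = 0.001
binom_band <- function(n, p) {
  stats::qbinom(c(0.0005, 0.9995), n, p)
}
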