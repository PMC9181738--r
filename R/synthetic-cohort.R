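#' Configuration for the synthetic multi-center perioperative cohort
#'
#' Defines the data-generating process for a multi-center cardiac-surgery
#' cohort: a pre-operative logistic risk structure with piecewise-linear
#' effects of age and creatinine clearance, per-center intraoperative
#' log-odds shifts mediated by observable ICU-admission severity variables,
#' Bernoulli hospital outcomes, and the registry messiness (re-admissions,
#' month-level record incompleteness, missing outcomes) the cohort filters
#' must handle.
#'
#' Covariate marginals default to values typical of a contemporary European
#' adult cardiac-surgery registry (median age 70, ~68% male, ~84% elective
#' surgery, ~3.6% hospital mortality).
#'
#' @param n_centers Number of centers (>= 1).
#' @param patients_per_center Scalar, or vector of length `n_centers`, of
#'   first-admission counts per center.
#' @param seed Integer seed; identical config implies byte-identical output.
#' @param preop_coefficients Named list of log-odds effects: `intercept`;
#'   `age` and `creatinine_clearance` as `list(knots=, slopes=)` (slopes are
#'   per-segment log-odds per unit); named vectors `sex`, `nyha`, `ef_class`,
#'   `urgency` (first element the reference); scalars for the binary flags
#'   `redo`, `avs`, `mvp`, `mvr`, `cabg`, `aa`.
#' @param center_intraop_shift Numeric vector (length `n_centers`) of
#'   per-center intraoperative log-odds shifts; the quantity the benchmark
#'   statistic d is designed to detect.
#' @param postop_noise_sd Standard deviation (log-odds) of the patient-level
#'   intraoperative contribution, carried by two observable ICU-admission
#'   severity variables.
#' @param readmission_rate Probability a patient has a second ICU admission.
#' @param incomplete_month_rate Probability a (center, month) stratum is
#'   degraded.
#' @param incomplete_record_rate_within Per-record probability of an
#'   incomplete record inside a degraded stratum.
#' @param missing_outcome_rate Probability the hospital outcome is missing.
#' @param pediatric_rate,icu_before_surgery_rate,typeb_rate Rates of records
#'   targeted by the inclusion/exclusion filters (age <= 16, ICU admission
#'   before surgery, Type-B dissection repair).
#' @param months Calendar months admissions are spread over.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_centers = 20,
    patients_per_center = 800,
    seed = 1L,
    preop_coefficients = default_preop_coefficients(),
    center_intraop_shift = seq(-0.45, 0.45, length.out = n_centers),
    postop_noise_sd = 0.5,
    readmission_rate = 0.02,
    incomplete_month_rate = 0.06,
    incomplete_record_rate_within = 0.30,
    missing_outcome_rate = 0.022,
    pediatric_rate = 0.003,
    icu_before_surgery_rate = 0.010,
    typeb_rate = 0.004,
    months = default_months()) {
  cfg <- structure(list(
    n_centers = n_centers,
    patients_per_center = patients_per_center,
    seed = seed,
    preop_coefficients = preop_coefficients,
    center_intraop_shift = center_intraop_shift,
    postop_noise_sd = postop_noise_sd,
    readmission_rate = readmission_rate,
    incomplete_month_rate = incomplete_month_rate,
    incomplete_record_rate_within = incomplete_record_rate_within,
    missing_outcome_rate = missing_outcome_rate,
    pediatric_rate = pediatric_rate,
    icu_before_surgery_rate = icu_before_surgery_rate,
    typeb_rate = typeb_rate,
    months = months
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

default_months <- function() {
  sprintf("%d-%02d", rep(2016:2017, each = 12), rep(1:12, 2))
}

#' @rdname synthetic_config
#' @export
default_preop_coefficients <- function() {
  list(
    # intercept calibrated so overall hospital mortality is ~3.6% at the
    # default case-mix, shifts and intraoperative noise
    intercept = -2.70,
    age = list(knots = 65, slopes = c(0.005, 0.110)),
    creatinine_clearance = list(knots = 65, slopes = c(-0.048, -0.002)),
    sex = c(female = 0, male = -0.15),
    nyha = c("I" = 0, "II" = 0.30, "III" = 0.45, "IV" = 1.30),
    ef_class = c(">50" = 0, "30-50" = 0.35, "<30" = 1.10),
    urgency = c(elective = 0, deferred = 0.55, emergent = 1.10,
                salvage = 2.30),
    redo = 0.60, avs = 0.10, mvp = -0.25, mvr = 0.35, cabg = -0.10,
    aa = 0.65
  )
}

validate_synthetic_config <- function(cfg) {
  prob_fields <- c("readmission_rate", "incomplete_month_rate",
                   "incomplete_record_rate_within", "missing_outcome_rate",
                   "pediatric_rate", "icu_before_surgery_rate", "typeb_rate")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_field(f, "must be a probability in [0, 1]")
    }
  }
  if (!is.numeric(cfg$n_centers) || cfg$n_centers < 1) {
    stop_field("n_centers", "must be >= 1")
  }
  npc <- cfg$patients_per_center
  if (!is.numeric(npc) || !length(npc) %in% c(1L, cfg$n_centers) ||
      any(npc < 1)) {
    stop_field("patients_per_center",
               "must be a positive scalar or vector of length n_centers")
  }
  if (!is.numeric(cfg$postop_noise_sd) || cfg$postop_noise_sd < 0) {
    stop_field("postop_noise_sd", "must be >= 0")
  }
  if (length(cfg$center_intraop_shift) != cfg$n_centers) {
    stop_field("center_intraop_shift",
               "must have one shift per center")
  }
  for (v in c("age", "creatinine_clearance")) {
    pw <- cfg$preop_coefficients[[v]]
    if (length(pw$knots) > 1 && any(diff(pw$knots) <= 0)) {
      stop_field(sprintf("preop_coefficients$%s$knots", v),
                 "must be strictly increasing")
    }
    if (length(pw$slopes) != length(pw$knots) + 1) {
      stop_field(sprintf("preop_coefficients$%s$slopes", v),
                 "needs one slope per segment (knots + 1)")
    }
  }
  invisible(cfg)
}

# Piecewise-linear contribution, continuous at the knots.
piecewise_value <- function(x, knots, slopes) {
  out <- slopes[1] * pmin(x, if (length(knots)) knots[1] else Inf)
  if (length(knots)) {
    bounds <- c(knots, Inf)
    for (j in seq_along(knots)) {
      seg <- pmin(pmax(x - knots[j], 0), bounds[j + 1] - knots[j])
      out <- out + slopes[j + 1] * seg
    }
  }
  out
}

# Pre-operative linear predictor under the generating coefficients.
linpred_preop <- function(data, coefs) {
  lp <- rep(coefs$intercept, nrow(data))
  lp <- lp + piecewise_value(data$age, coefs$age$knots, coefs$age$slopes)
  lp <- lp + piecewise_value(data$creatinine_clearance,
                             coefs$creatinine_clearance$knots,
                             coefs$creatinine_clearance$slopes)
  lp <- lp + unname(coefs$sex[data$sex])
  lp <- lp + unname(coefs$nyha[data$nyha])
  lp <- lp + unname(coefs$ef_class[data$ef_class])
  lp <- lp + unname(coefs$urgency[data$urgency])
  for (flag in c("redo", "avs", "mvp", "mvr", "cabg", "aa")) {
    lp <- lp + coefs[[flag]] * as.numeric(data[[flag]])
  }
  lp
}

#' Generate a synthetic multi-center cohort with known ground truth
#'
#' One row per ICU admission. The post-operative linear predictor is the
#' pre-operative one plus the center's intraoperative shift plus a
#' patient-level intraoperative contribution; both are carried by two
#' observable ICU-admission severity variables (`icu_lactate`,
#' `icu_severity`) so that a post-operative model fitted without a center
#' term can detect the shift — as in a real registry, where a center's
#' intraoperative performance is visible only through the state patients
#' arrive in at the ICU.
#'
#' Ground truth: the per-patient true post-operative probability is the
#' generating probability; the true pre-operative probability is the
#' marginal probability over the patient-level intraoperative contribution
#' at the zero-shift (average-center) reference, computed by Gauss-Hermite
#' quadrature. True per-center `e_pre`, `e_post` and `d` are sums/ratios of
#' these over the center's inclusion-eligible first admissions.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (data frame, one row per admission) and
#'   `true_values` (class `true_values`: `$patients` per-row truth,
#'   `$centers` per-center truth).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  npc <- rep(cfg$patients_per_center, length.out = cfg$n_centers)
  n <- sum(npc)
  centers <- sprintf("C%02d", seq_len(cfg$n_centers))
  shifts <- stats::setNames(as.numeric(cfg$center_intraop_shift), centers)

  withr::with_seed(cfg$seed, {
    center_id <- rep(centers, times = npc)
    age <- round(pmin(pmax(stats::rnorm(n, 69.5, 10.5), 18), 95))
    ped <- stats::runif(n) < cfg$pediatric_rate
    age[ped] <- round(stats::runif(sum(ped), 6, 16))
    sex <- ifelse(stats::runif(n) < 0.676, "male", "female")
    nyha <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.502, 0.28, 0.183, 0.035))
    ef_class <- sample(c(">50", "30-50", "<30"), n, replace = TRUE,
                       prob = c(0.678, 0.296, 0.026))
    urgency <- sample(c("elective", "deferred", "emergent", "salvage"), n,
                      replace = TRUE, prob = c(0.838, 0.086, 0.070, 0.006))
    creatinine_clearance <- pmin(pmax(
      stats::rlnorm(n, meanlog = log(74), sdlog = 0.40), 5), 180)
    redo <- stats::runif(n) < 0.068
    avs <- stats::runif(n) < 0.352
    mvp <- stats::runif(n) < 0.112
    mvr <- stats::runif(n) < 0.116 & !mvp
    cabg <- stats::runif(n) < 0.480
    aa <- stats::runif(n) < 0.113
    icu_before_surgery <- stats::runif(n) < cfg$icu_before_surgery_rate
    typeb_dissection_repair <- stats::runif(n) < cfg$typeb_rate
    admission_month <- sample(cfg$months, n, replace = TRUE)
    day <- sample(28, n, replace = TRUE)

    base <- data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      center_id = center_id,
      admission_month = admission_month,
      admission_ts = sprintf("%s-%02d", admission_month, day),
      readmission_index = 1L,
      age = age, sex = sex, nyha = nyha, ef_class = ef_class,
      urgency = urgency, creatinine_clearance = creatinine_clearance,
      redo = redo, avs = avs, mvp = mvp, mvr = mvr, cabg = cabg, aa = aa,
      icu_before_surgery = icu_before_surgery,
      typeb_dissection_repair = typeb_dissection_repair,
      stringsAsFactors = FALSE
    )

    lp_pre <- linpred_preop(base, cfg$preop_coefficients)
    shift <- unname(shifts[base$center_id])
    s <- cfg$postop_noise_sd
    gamma <- s / sqrt(2)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    if (gamma > 0) {
      mu <- shift / (2 * gamma)
      base$icu_lactate <- z1 + mu
      base$icu_severity <- z2 + mu
      lp_post <- lp_pre + gamma * (base$icu_lactate + base$icu_severity)
    } else {
      base$icu_lactate <- z1
      base$icu_severity <- z2
      lp_post <- lp_pre + shift
    }
    p_post <- stats::plogis(lp_post)
    dead <- stats::rbinom(n, 1, p_post) == 1
    base$hospital_outcome <- ifelse(dead, "dead", "alive")

    # re-admissions: duplicated patients with a later admission
    re <- which(stats::runif(n) < cfg$readmission_rate)
    cohort <- base
    if (length(re)) {
      dup <- base[re, , drop = FALSE]
      mi <- match(dup$admission_month, cfg$months)
      mi2 <- pmin(mi + 1L, length(cfg$months))
      dup$admission_month <- cfg$months[mi2]
      dup$admission_ts <- sprintf("%s-%02d", dup$admission_month,
                                  sample(28, length(re), replace = TRUE))
      dup$readmission_index <- 2L
      dup$hospital_outcome <- ifelse(
        stats::rbinom(length(re), 1, p_post[re]) == 1, "dead", "alive")
      cohort <- rbind(base, dup)
    }

    # month-level incompleteness, clustered by (center, month)
    strata <- unique(cohort[, c("center_id", "admission_month")])
    degraded <- stats::runif(nrow(strata)) < cfg$incomplete_month_rate
    key <- paste(cohort$center_id, cohort$admission_month)
    dkey <- paste(strata$center_id, strata$admission_month)[degraded]
    cohort$complete <- TRUE
    in_deg <- key %in% dkey
    cohort$complete[in_deg] <-
      stats::runif(sum(in_deg)) >= cfg$incomplete_record_rate_within

    miss <- stats::runif(nrow(cohort)) < cfg$missing_outcome_rate
    cohort$hospital_outcome[miss] <- "missing"

    ord <- order(cohort$center_id, cohort$admission_ts, cohort$patient_id,
                 cohort$readmission_index)
    cohort <- cohort[ord, , drop = FALSE]
    rownames(cohort) <- NULL
    cohort$row_id <- seq_len(nrow(cohort))

    # ground truth, on first admissions
    p_pre_true <- logistic_normal_marginal(lp_pre, s)
    included <- base$age > 16 & !base$typeb_dissection_repair &
      !base$icu_before_surgery
    patients <- data.frame(
      patient_id = base$patient_id,
      center_id = base$center_id,
      included = included,
      p_pre = p_pre_true,
      p_post = p_post,
      stringsAsFactors = FALSE
    )
    agg <- lapply(centers, function(cc) {
      sel <- patients$included & patients$center_id == cc
      e_pre <- sum(patients$p_pre[sel])
      e_post <- sum(patients$p_post[sel])
      data.frame(center_id = cc, n = sum(sel), e_pre = e_pre,
                 e_post = e_post,
                 d = if (e_pre > 0) (e_post - e_pre) / e_pre else NA_real_,
                 stringsAsFactors = FALSE)
    })
    true_values <- structure(list(
      patients = patients,
      centers = do.call(rbind, agg),
      postop_noise_sd = s,
      center_intraop_shift = shifts
    ), class = "true_values")

    list(cohort = cohort, true_values = true_values)
  })
}

#' True relative difference in expected deaths for one center
#'
#' Computed from the generating probabilities, never from outcomes:
#' `d = (e_post - e_pre) / e_pre` over the center's inclusion-eligible
#' first admissions.
#'
#' @param true_values A `true_values` object from [generate_cohort()].
#' @param center Center id (e.g. `"C03"`).
#' @return The exact ratio.
#' @export
true_center_d <- function(true_values, center) {
  stopifnot(inherits(true_values, "true_values"))
  row <- true_values$centers[true_values$centers$center_id == center, ]
  if (nrow(row) != 1 || row$n < 1) {
    stop(sprintf("center `%s` not present with >= 1 patient", center),
         call. = FALSE)
  }
  if (row$e_pre <= 0) {
    stop(sprintf("center `%s` has true e_pre = 0; d is undefined", center),
         call. = FALSE)
  }
  (row$e_post - row$e_pre) / row$e_pre
}

#' Candidate variable dictionary for the synthetic cohort
#'
#' @param stage `"pre"` or `"post"`.
#' @return Data frame with columns `variable`, `type`
#'   (`continuous`/`categorical`/`binary`) and `stage`.
#' @export
candidate_dictionary <- function(stage = c("pre", "post")) {
  stage <- match.arg(stage)
  pre <- data.frame(
    variable = c("age", "creatinine_clearance", "sex", "nyha", "ef_class",
                 "urgency", "redo", "avs", "mvp", "mvr", "cabg", "aa"),
    type = c("continuous", "continuous", "categorical", "categorical",
             "categorical", "categorical", rep("binary", 6)),
    stage = "pre", stringsAsFactors = FALSE)
  post <- data.frame(
    variable = c("icu_lactate", "icu_severity"),
    type = "continuous", stage = "post", stringsAsFactors = FALSE)
  if (stage == "pre") pre else post
}

#' Write / read a cohort as CSV
#'
#' Plain-text round trip of the cohort table; logical flags are stored as
#' TRUE/FALSE strings.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("redo", "avs", "mvp", "mvr", "cabg", "aa",
              "icu_before_surgery", "typeb_dissection_repair", "complete")) {
    if (f %in% names(df)) df[[f]] <- as.logical(df[[f]])
  }
  df
}
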