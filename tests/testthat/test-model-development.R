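test_that("fit_logistic matches closed forms on 2x2 and intercept-only data", {
  # exposure log-OR: a=10/40 exposed, c=5/45 unexposed
  cohort <- counts_cohort(10, 40, 5, 45)
  X <- cbind(`(Intercept)` = 1, exposure = as.numeric(cohort$exposure))
  y <- as.integer(cohort$hospital_outcome == "dead")
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients["exposure"]),
               log((10 * 45) / (40 * 5)), tolerance = 1e-6)

  # intercept-only: 3 deaths in 10
  f0 <- fit_logistic(matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")),
                     rep(c(1, 0), c(3, 7)))
  expect_equal(unname(f0$coefficients), qlogis(0.3), tolerance = 1e-8)

  # canonical-link score equation: fitted probabilities sum to deaths
  expect_equal(sum(fit$fitted), 15, tolerance = 1e-6)
})

test_that("fit_logistic rejects rank-deficient and separated designs", {
  X <- cbind(`(Intercept)` = 1, a = rep(c(0, 1), 10), b = rep(c(0, 2), 10))
  y <- rep(c(0, 1, 0, 1), 5)
  expect_error(fit_logistic(X, y), "collinear.*b")

  Xs <- cbind(`(Intercept)` = 1, x = c(rep(0, 10), rep(1, 10)))
  ys <- rep(c(0, 1), c(10, 10))
  expect_error(fit_logistic(Xs, ys), "separat")
  f <- fit_logistic(Xs, ys, allow_separation = TRUE)
  expect_true(f$separation)
})

test_that("risk model JSON round trip preserves structure and predictions", {
  g <- generate_cohort(quick_config(n_centers = 2, npc = 600, seed = 2))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  terms <- list(term_piecewise("age", 60),
                term_categorical("nyha", levels = c("I", "II", "III", "IV"),
                                 levels_map = c(I = "I", II = "II-III",
                                                III = "II-III", IV = "IV")),
                term_binary("cabg"))
  m <- fit_risk_model(cohort, terms, "pre")
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  m2 <- read_risk_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(predict(m2, cohort), predict(m, cohort))
  expect_equal(vapply(m2$terms, `[[`, character(1), "type"),
               vapply(m$terms, `[[`, character(1), "type"))
})

test_that("rare-variable screening applies the strict count thresholds", {
  base <- data.frame(hospital_outcome = rep("alive", 2000))
  mk <- function(n_exposed, deaths_exposed) {
    x <- rep(FALSE, 2000); x[seq_len(n_exposed)] <- TRUE
    out <- base
    out$flag <- x
    out$hospital_outcome[seq_len(deaths_exposed)] <- "dead"
    # plenty of events overall so only the subgroup counts matter
    out$hospital_outcome[1500:1999] <- "dead"
    out
  }
  cands <- list(flag = term_binary("flag"))
  cfg <- selection_config()
  # 99 exposed patients: dropped
  expect_true("flag" %in%
    screen_rare_variables(mk(99, 50), cands, cfg)$dropped)
  # 150 patients but 29 deaths among them: dropped
  expect_true("flag" %in%
    screen_rare_variables(mk(150, 29), cands, cfg)$dropped)
  # exactly 100 patients and 30 deaths: kept (strict 'less than')
  res <- screen_rare_variables(mk(100, 30), cands, cfg)
  expect_true("flag" %in% names(res$kept))
})

test_that("rare categorical levels are merged into their neighbour", {
  n <- 3000
  withr::with_seed(8, {
    x <- sample(c("elective", "deferred", "emergent", "salvage"), n,
                replace = TRUE, prob = c(0.85, 0.08, 0.055, 0.015))
    y <- rbinom(n, 1, 0.2)
  })
  cohort <- data.frame(urgency = x,
                       hospital_outcome = ifelse(y == 1, "dead", "alive"))
  cands <- list(urgency = term_categorical(
    "urgency", levels = c("elective", "deferred", "emergent", "salvage")))
  res <- screen_rare_variables(cohort, cands, selection_config())
  term <- res$kept$urgency
  expect_false(is.null(term$levels_map))
  expect_equal(unname(term$levels_map["salvage"]), "emergent")
  lev <- dualbench:::term_coded_levels(term, cohort)
  expect_equal(lev, c("elective", "deferred", "emergent"))
})

test_that("bivariate screen matches the closed-form 2x2 likelihood-ratio", {
  # exposed: 100 with 5 deaths; unexposed: 900 with 9 deaths
  cohort <- counts_cohort(5, 95, 9, 891)
  names(cohort)[1] <- "exposure"
  res <- bivariate_screen(cohort, list(exposure = term_binary("exposure")),
                          selection_config())
  ll <- function(k, n) {
    p <- k / n
    k * log(p) + (n - k) * log(1 - p)
  }
  # saturated-by-group vs pooled binomial log-likelihoods
  stat <- 2 * (ll(5, 100) + ll(9, 900) - ll(14, 1000))
  p_oracle <- pchisq(stat, df = 1, lower.tail = FALSE)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(res$kept, p_oracle <= 0.25)
})

test_that("a variable identical to the outcome raises the separation flag", {
  cohort <- data.frame(hospital_outcome = rep(c("dead", "alive"), c(30, 70)))
  cohort$mirror <- cohort$hospital_outcome == "dead"
  res <- bivariate_screen(cohort, list(mirror = term_binary("mirror")),
                          selection_config())
  expect_true(res$separation)
  expect_true(res$kept)
})

test_that("piecewise fit keeps a linear logit linear", {
  zero_knots <- 0
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      x <- runif(2000, 20, 100)
      y <- rbinom(2000, 1, plogis(-4 + 0.03 * x))
    })
    cohort <- data.frame(clearance = x,
                         hospital_outcome = ifelse(y == 1, "dead", "alive"))
    tr <- fit_piecewise(cohort, "clearance")
    if (length(tr$knots) == 0) zero_knots <- zero_knots + 1
  }
  expect_gte(zero_knots, 17)
})

test_that("piecewise fit recovers a hinge-shaped risk", {
  withr::with_seed(77, {
    x <- runif(6000, 20, 100)
    lp <- -1.2 - 0.08 * pmin(x - 60, 0)  # falling below 60, flat above
    y <- rbinom(6000, 1, plogis(lp))
  })
  cohort <- data.frame(clearance = x,
                       hospital_outcome = ifelse(y == 1, "dead", "alive"))
  tr <- fit_piecewise(cohort, "clearance")
  expect_gte(length(tr$knots), 1)
  expect_lte(min(abs(tr$knots - 60)), 10)
  expect_lt(tr$slopes[1], 0)  # falling segment recovered

  const <- data.frame(clearance = rep(1, 100),
                      hospital_outcome = rep(c("dead", "alive"), 50))
  expect_error(fit_piecewise(const, "clearance"), "constant")
})

test_that("forcing every candidate bypasses selection", {
  g <- generate_cohort(quick_config(n_centers = 2, npc = 800, seed = 6))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  cands <- list(age = term_linear("age"), cabg = term_binary("cabg"),
                mvr = term_binary("mvr"))
  sel <- stepwise_select(cohort, cands, selection_config(), forced = cands)
  full <- fit_risk_model(cohort, cands, "pre")
  expect_equal(sel$coefficients, full$coefficients, tolerance = 1e-8)
  expect_equal(sel$forced, c("age", "cabg", "mvr"))
})

test_that("stepwise selection finds a strong covariate and reports a trace", {
  withr::with_seed(5, {
    n <- 4000
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-2.5 + x1))
  })
  cohort <- data.frame(x1 = x1, x2 = x2, x3 = x3,
                       hospital_outcome = ifelse(y == 1, "dead", "alive"))
  cands <- list(x1 = term_linear("x1"), x2 = term_linear("x2"),
                x3 = term_linear("x3"))
  m <- stepwise_select(cohort, cands, selection_config())
  expect_true("x1" %in% m$selected)
  expect_true(m$converged)
})

test_that("indistinguishable categorical levels are merged, distinct kept", {
  withr::with_seed(12, {
    n <- 9000
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    lp <- -2 + ifelse(g == "A", 0, 0.8)  # B and C share the same effect
    y <- rbinom(n, 1, plogis(lp))
  })
  cohort <- data.frame(grp = g,
                       hospital_outcome = ifelse(y == 1, "dead", "alive"))
  term <- term_categorical("grp", levels = c("A", "B", "C"))
  m <- fit_risk_model(cohort, list(term), "pre")
  merged <- merge_levels(m, cohort, "grp")
  lev <- dualbench:::term_coded_levels(merged$terms[[1]], cohort)
  expect_equal(length(lev), 2)
  expect_true(any(grepl("B-C", lev)))

  withr::with_seed(13, {
    lp2 <- -2 + ifelse(g == "A", 0, ifelse(g == "B", 0.8, 1.8))
    y2 <- rbinom(n, 1, plogis(lp2))
  })
  cohort2 <- data.frame(grp = g,
                        hospital_outcome = ifelse(y2 == 1, "dead", "alive"))
  m2 <- fit_risk_model(cohort2, list(term), "pre")
  merged2 <- merge_levels(m2, cohort2, "grp")
  expect_equal(length(dualbench:::term_coded_levels(merged2$terms[[1]],
                                                    cohort2)), 3)

  # clinical grouping config can veto a merge
  vetoed <- merge_levels(m, cohort, "grp",
                         allowed_groups = list(c("A", "B")))
  expect_equal(length(dualbench:::term_coded_levels(vetoed$terms[[1]],
                                                    cohort)), 3)
})

test_that("post-operative model keeps all pre-operative terms", {
  g <- generate_cohort(quick_config(n_centers = 3, npc = 1500, seed = 14,
                                    shifts = c(-0.3, 0, 0.3), sd = 0.7))
  cohort <- exclude_missing_outcome(g$cohort)$cohort
  pre <- fit_risk_model(cohort, list(term_piecewise("age", 60),
                                     term_binary("mvr")), "pre")
  post_cands <- list(icu_lactate = term_linear("icu_lactate"),
                     icu_severity = term_linear("icu_severity"))
  post <- build_postop_model(cohort, pre, post_cands)
  pre_names <- vapply(pre$terms, `[[`, character(1), "name")
  post_names <- vapply(post$terms, `[[`, character(1), "name")
  expect_true(all(pre_names %in% post_names))  # nesting invariant
  expect_true(all(c("icu_lactate", "icu_severity") %in% post_names))

  # no post-op candidates: exactly the pre-op terms, refitted
  post0 <- build_postop_model(cohort, pre, list())
  expect_equal(vapply(post0$terms, `[[`, character(1), "name"), pre_names)
  expect_equal(post0$stage, "post")
})
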