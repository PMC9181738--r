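#' Maximum-likelihood logistic regression on a design matrix
#'
#' Thin, strict wrapper around [stats::glm.fit()] (IRLS with the logit
#' link): checks the design for rank deficiency before fitting, flags
#' (quasi-)separation afterwards, and returns the pieces the rest of the
#' pipeline needs (coefficients, covariance, deviance).
#'
#' Convergence follows `glm.control(epsilon = 1e-10, maxit = 100)`, i.e.
#' the relative deviance change must fall below `1e-10` within 100
#' iterations.
#'
#' @param design Numeric design matrix including an intercept column.
#' @param outcome Binary 0/1 vector.
#' @param start Optional starting coefficients (used by the bootstrap to
#'   warm-start refits).
#' @param allow_separation If `TRUE`, a separated fit is returned with
#'   `separation = TRUE` instead of erroring (used by screening, which must
#'   flag rather than fail).
#' @return Object of class `logit_fit`: list with `coefficients`, `vcov`,
#'   `deviance`, `null_deviance`, `df_residual`, `fitted`, `converged`,
#'   `separation`, `n`.
#' @export
fit_logistic <- function(design, outcome, start = NULL,
                         allow_separation = FALSE) {
  X <- as.matrix(design)
  y <- as.numeric(outcome)
  if (any(is.na(X)) || any(is.na(y))) {
    stop("design/outcome contain missing values; restrict to complete cases",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    start = start,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # perfect separation collapses the deviance; quasi-separation shows up as
  # a diverging coefficient, judged on the covariate's own scale
  col_sd <- if (ncol(X) > 1) {
    apply(X[, -1, drop = FALSE], 2, stats::sd)
  } else numeric(0)
  std_beta <- abs(beta[-1]) * col_sd
  separated <- fit$deviance < 1e-6 ||
    (length(std_beta) && max(std_beta, na.rm = TRUE) > 15)
  if (separated && !allow_separation) {
    stop("fit is (quasi-)separated: fitted probabilities degenerate",
         call. = FALSE)
  }
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = vc,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    df_residual = fit$df.residual,
    fitted = mu,
    converged = fit$converged,
    separation = separated,
    n = length(y)
  ), class = "logit_fit")
}

# Likelihood-ratio test p-value for nested logit fits.
lrt_pvalue <- function(fit_small, fit_big, df = NULL) {
  if (is.null(df)) {
    df <- length(fit_big$coefficients) - length(fit_small$coefficients)
  }
  stat <- fit_small$deviance - fit_big$deviance
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Fit a risk model from a term list
#'
#' Builds the design matrix from `terms`, restricts to complete cases
#' (complete-case counts are recorded), and fits by maximum likelihood.
#'
#' @param cohort Cohort data frame.
#' @param terms List of [risk_terms] describing the linear predictor.
#' @param stage `"pre"` or `"post"`; bookkeeping only.
#' @param outcome_col Name of the outcome column (`alive`/`dead`).
#' @return Object of class `risk_model` with elements `stage`, `terms`,
#'   `coefficients`, `vcov`, `deviance`, `null_deviance`, `converged`,
#'   `n`, `n_dropped_incomplete`, `events`.
#' @export
fit_risk_model <- function(cohort, terms, stage = c("pre", "post"),
                           outcome_col = "hospital_outcome") {
  stage <- match.arg(stage)
  y <- outcome_binary(cohort, outcome_col)
  X <- build_design(cohort, terms)
  ok <- stats::complete.cases(X) & !is.na(y)
  fit <- fit_logistic(X[ok, , drop = FALSE], y[ok])
  structure(list(
    stage = stage,
    terms = terms,
    coefficients = fit$coefficients,
    vcov = fit$vcov,
    deviance = fit$deviance,
    null_deviance = fit$null_deviance,
    converged = fit$converged,
    n = sum(ok),
    n_dropped_incomplete = sum(!ok),
    events = sum(y[ok])
  ), class = "risk_model")
}

#' Predicted death probabilities from a fitted risk model
#'
#' @param object A `risk_model`.
#' @param newdata Cohort data frame to score.
#' @param ... Unused.
#' @return Numeric vector of probabilities (NA where covariates are missing).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  X <- build_design(newdata, object$terms)
  drop(stats::plogis(X %*% object$coefficients))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model stage=%s: %d terms, n=%d, events=%d, deviance=%.2f>\n",
              x$stage, length(x$terms), x$n, x$events, x$deviance))
  or <- exp(x$coefficients)
  print(data.frame(coef = round(x$coefficients, 4), OR = round(or, 3)))
  invisible(x)
}

#' Serialise / restore a fitted risk model as JSON
#'
#' The JSON records the term structure (including knots and merged-level
#' maps), coefficients and covariance, so a model can be archived and
#' re-applied to new cohorts.
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @export
write_risk_model <- function(model, path) {
  payload <- list(
    stage = model$stage,
    terms = lapply(model$terms, function(t) {
      t <- unclass(t)
      if (!is.null(t$levels_map)) t$levels_map <- as.list(t$levels_map)
      t
    }),
    coefficients = as.list(model$coefficients),
    vcov = model$vcov,
    deviance = model$deviance,
    null_deviance = model$null_deviance,
    n = model$n,
    events = model$events
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(p$terms, function(t) {
    out <- list(name = t$name, type = t$type)
    if (!is.null(t$knots)) out$knots <- as.numeric(unlist(t$knots))
    if (!is.null(t$levels)) out$levels <- as.character(unlist(t$levels))
    if (!is.null(t$levels_map)) {
      out$levels_map <- vapply(t$levels_map, as.character, character(1))
    }
    structure(out, class = "risk_term")
  })
  cf <- vapply(p$coefficients, as.numeric, numeric(1))
  vc <- do.call(rbind, lapply(p$vcov, function(r) as.numeric(unlist(r))))
  dimnames(vc) <- list(names(cf), names(cf))
  structure(list(stage = p$stage, terms = terms,
                 coefficients = cf, vcov = vc,
                 deviance = p$deviance, null_deviance = p$null_deviance,
                 converged = TRUE, n = p$n, events = p$events),
            class = "risk_model")
}
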