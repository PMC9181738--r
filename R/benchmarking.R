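#' Expected deaths from predicted probabilities
#'
#' The expected number of deaths in a group of patients is the sum of
#' their predicted death probabilities; on the training set of a converged
#' logistic fit this equals the observed death count (canonical-link score
#' equation).
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @return Their sum (0 for an empty set).
#' @export
expected_deaths <- function(probabilities) {
  if (!length(probabilities)) return(0)
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  sum(probabilities, na.rm = TRUE)
}

#' Relative difference in expected deaths
#'
#' `d = (e_post - e_pre) / e_pre`: the change in expected mortality across
#' the intraoperative period, normalised by the pre-operative expectation.
#' Positive values mean predicted risk increased after surgery.
#'
#' @param e_pre Pre-operative expected deaths (> 0).
#' @param e_post Post-operative expected deaths.
#' @return The exact ratio.
#' @export
relative_difference <- function(e_pre, e_post) {
  if (any(e_pre <= 0)) {
    stop("e_pre must be > 0: d is undefined for zero expected deaths",
         call. = FALSE)
  }
  (e_post - e_pre) / e_pre
}

#' Standard patient subgroups for benchmarking
#'
#' Urgency strata (elective vs non-elective) and procedure types: aortic
#' valve surgery (AVS), mitral valve surgery (MVS, split into repair MVP
#' and replacement MVR), CABG, and ascending aorta surgery (AA).
#'
#' @return Named list of predicate functions over a cohort.
#' @export
default_subgroups <- function() {
  list(
    elective = function(d) d$urgency == "elective",
    non_elective = function(d) d$urgency != "elective",
    AVS = function(d) d$avs,
    MVS = function(d) d$mvp | d$mvr,
    MVP = function(d) d$mvp,
    MVR = function(d) d$mvr,
    CABG = function(d) d$cabg,
    AA = function(d) d$aa
  )
}

#' Benchmark centers and subgroups with bootstrap confidence intervals
#'
#' For every center, overall and within each subgroup: the number of
#' patients, expected deaths under the pre- and post-operative models
#' (`e_pre`, `e_post`), the relative difference `d`, and a percentile 95%
#' confidence interval from `B` bootstrap replicates. In each replicate
#' the full cohort is resampled with replacement (optionally stratified by
#' center), both models are re-estimated with fixed term structure —
#' coefficients refitted, never carried over — and `d` is recomputed per
#' unit from the resampled records; a unit with zero resampled `e_pre`
#' contributes a missing value to that replicate, and a confidence
#' interval is only reported when at least `min_usable` of the replicates
#' were usable.
#'
#' @param cohort Scored cohort (non-missing outcomes).
#' @param preop_model,postop_model Fitted `risk_model`s.
#' @param subgroups Named list of predicate functions (see
#'   [default_subgroups()]); `NULL` benchmarks centers overall only.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed; same (data, B, seed) gives identical CIs.
#' @param stratified Resample within centers instead of the whole cohort.
#' @param min_usable Minimum fraction of usable replicates for a CI
#'   (default 0.8).
#' @return Data frame of class `center_benchmark`: `unit`, `center_id`,
#'   `subgroup`, `n`, `e_pre`, `e_post`, `d`, `ci_low`, `ci_high`, `B`,
#'   `n_usable`. Units with zero patients are omitted with a warning.
#' @export
benchmark_centers <- function(cohort, preop_model, postop_model,
                              subgroups = default_subgroups(),
                              B = 1000, seed = 1L, stratified = FALSE,
                              min_usable = 0.8) {
  stopifnot(inherits(preop_model, "risk_model"),
            inherits(postop_model, "risk_model"))
  if (B < 1) stop_field("B", "must be >= 1")
  y <- outcome_binary(cohort)
  X_pre <- build_design(cohort, preop_model$terms)
  X_post <- build_design(cohort, postop_model$terms)
  ok <- !is.na(y) & stats::complete.cases(X_pre) &
    stats::complete.cases(X_post)
  if (!all(ok)) {
    message(sprintf("benchmark: dropping %d record(s) with missing data",
                    sum(!ok)))
  }
  dat <- cohort[ok, , drop = FALSE]
  y <- y[ok]
  X_pre <- X_pre[ok, , drop = FALSE]
  X_post <- X_post[ok, , drop = FALSE]
  n <- nrow(dat)
  center <- as.character(dat$center_id)
  centers <- sort(unique(center))

  masks <- c(list(overall = rep(TRUE, n)),
             lapply(subgroups, function(f) {
               m <- f(dat)
               m & !is.na(m)
             }))

  beta_pre <- preop_model$coefficients
  beta_post <- postop_model$coefficients
  p_pre <- drop(stats::plogis(X_pre %*% beta_pre))
  p_post <- drop(stats::plogis(X_post %*% beta_post))

  units <- list(); skipped <- character()
  for (cc in centers) {
    in_c <- center == cc
    for (sg in names(masks)) {
      sel <- in_c & masks[[sg]]
      if (!sum(sel)) {
        skipped <- c(skipped, sprintf("%s/%s", cc, sg))
        next
      }
      e_pre <- sum(p_pre[sel]); e_post <- sum(p_post[sel])
      units[[length(units) + 1]] <- list(
        center = cc, subgroup = sg, sel = which(sel), n = sum(sel),
        e_pre = e_pre, e_post = e_post,
        d = if (e_pre > 0) (e_post - e_pre) / e_pre else NA_real_)
    }
  }
  if (length(skipped)) {
    warning(sprintf("omitting %d empty unit(s): %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  }

  # unit membership as an index into a per-(center x subgroup) accumulator
  unit_of_row <- lapply(units, `[[`, "sel")
  d_boot <- matrix(NA_real_, nrow = B, ncol = length(units))
  row_in_unit <- lapply(units, function(u) {
    v <- logical(n); v[u$sel] <- TRUE; v
  })

  center_idx <- split(seq_len(n), center)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- if (stratified) {
        unlist(lapply(center_idx, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]),
          use.names = FALSE)
      } else {
        sample.int(n, n, replace = TRUE)
      }
      yb <- y[idx]
      f_pre <- .irls_logit(X_pre[idx, , drop = FALSE], yb, beta_pre)
      f_post <- .irls_logit(X_post[idx, , drop = FALSE], yb, beta_post)
      if (!f_pre$converged || !f_post$converged) next
      pb_pre <- drop(stats::plogis(X_pre[idx, , drop = FALSE] %*%
                                     f_pre$coefficients))
      pb_post <- drop(stats::plogis(X_post[idx, , drop = FALSE] %*%
                                      f_post$coefficients))
      for (u in seq_along(units)) {
        inb <- row_in_unit[[u]][idx]
        e_pre_b <- sum(pb_pre[inb])
        if (e_pre_b > 0) {
          d_boot[b, u] <- (sum(pb_post[inb]) - e_pre_b) / e_pre_b
        }
      }
    }
  })

  rows <- lapply(seq_along(units), function(u) {
    db <- d_boot[, u]
    usable <- sum(!is.na(db))
    ci <- if (usable >= min_usable * B) {
      stats::quantile(db, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    } else c(NA_real_, NA_real_)
    un <- units[[u]]
    data.frame(unit = paste0(un$center,
                             ifelse(un$subgroup == "overall", "",
                                    paste0(":", un$subgroup))),
               center_id = un$center, subgroup = un$subgroup,
               n = un$n, e_pre = un$e_pre, e_post = un$e_post, d = un$d,
               ci_low = ci[1], ci_high = ci[2], B = B, n_usable = usable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("center_benchmark", "data.frame")
  out
}

#' Forest-plot table of center benchmarks
#'
#' Sorted ascending in `d`, ready for forest plotting.
#'
#' @param benchmarks A `center_benchmark` data frame.
#' @param subgroup Restrict to one subgroup (default `"overall"`; `NULL`
#'   keeps all units).
#' @return Data frame with `unit`, `d`, `ci_low`, `ci_high`, `n`, `e_pre`,
#'   `e_post`, ordered by `d`.
#' @export
export_forest <- function(benchmarks, subgroup = "overall") {
  stopifnot(nrow(benchmarks) > 0)
  tab <- as.data.frame(benchmarks)
  if (!is.null(subgroup)) {
    tab <- tab[tab$subgroup == subgroup, , drop = FALSE]
    if (!nrow(tab)) {
      warning(sprintf("no units in subgroup `%s`; returning empty table",
                      subgroup))
    }
  }
  tab <- tab[order(tab$d), c("unit", "d", "ci_low", "ci_high", "n",
                             "e_pre", "e_post")]
  rownames(tab) <- NULL
  tab
}
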