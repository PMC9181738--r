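#' Cohort filters, train/validation split and flowchart reporting
#'
#' The filters reproduce a fixed, documented exclusion order so that
#' flowchart tables are comparable across runs:
#' age (> 16 retained) -> Type-B dissection repair -> ICU admission before
#' surgery -> re-admissions (first admission only), then the month-level
#' completeness rule, then exclusion of missing outcomes.
#'
#' @name cohort_pipeline
NULL

new_filter_report <- function(step, n_in, n_excluded) {
  structure(data.frame(step = step, n_in = n_in, n_excluded = n_excluded,
                       n_out = n_in - n_excluded, stringsAsFactors = FALSE),
            class = c("filter_report", "data.frame"))
}

require_columns <- function(cohort, cols) {
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop(sprintf("required column(s) missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Apply the study inclusion/exclusion criteria
#'
#' Retains adults over 16 years, excludes Type-B aortic dissection repairs
#' and patients admitted to the ICU before surgery, and keeps only each
#' patient's first ICU admission. "Over 16" is read strictly: age 16 is
#' excluded, age 17 retained.
#'
#' @param cohort Cohort data frame.
#' @return List with `cohort` (filtered) and `report` (a `filter_report`
#'   with one row per exclusion step, in fixed order).
#' @export
apply_inclusion_exclusion <- function(cohort) {
  require_columns(cohort, c("age", "typeb_dissection_repair",
                            "icu_before_surgery", "patient_id",
                            "readmission_index"))
  steps <- list()
  n0 <- nrow(cohort)
  keep <- cohort$age > 16
  steps[[1]] <- new_filter_report("age_over_16", n0, sum(!keep))
  cohort <- cohort[keep, , drop = FALSE]

  keep <- !cohort$typeb_dissection_repair
  steps[[2]] <- new_filter_report("typeb_dissection_repair", nrow(cohort) + 0,
                                  sum(!keep))
  cohort <- cohort[keep, , drop = FALSE]

  keep <- !cohort$icu_before_surgery
  steps[[3]] <- new_filter_report("icu_before_surgery", nrow(cohort),
                                  sum(!keep))
  cohort <- cohort[keep, , drop = FALSE]

  keep <- cohort$readmission_index == 1
  steps[[4]] <- new_filter_report("first_admission_only", nrow(cohort),
                                  sum(!keep))
  cohort <- cohort[keep, , drop = FALSE]

  report <- do.call(rbind, steps)
  class(report) <- c("filter_report", "data.frame")
  list(cohort = cohort, report = report)
}

#' Month-level completeness filter
#'
#' Removes all records — including the complete ones — in any
#' (center, month) stratum whose fraction of incomplete records strictly
#' exceeds `threshold`. A stratum at exactly the threshold is retained.
#'
#' @param cohort Cohort data frame with `complete`, `center_id` and
#'   `admission_month` columns.
#' @param threshold Maximum tolerated incomplete fraction (default 0.10).
#' @return List with `cohort` and `report`.
#' @export
month_completeness_filter <- function(cohort, threshold = 0.10) {
  require_columns(cohort, c("complete", "center_id", "admission_month"))
  n0 <- nrow(cohort)
  if (n0 == 0) {
    return(list(cohort = cohort,
                report = new_filter_report("month_completeness", 0L, 0L)))
  }
  key <- paste(cohort$center_id, cohort$admission_month)
  frac <- tapply(!cohort$complete, key, mean)
  bad <- names(frac)[frac > threshold]
  keep <- !(key %in% bad)
  list(cohort = cohort[keep, , drop = FALSE],
       report = new_filter_report("month_completeness", n0, sum(!keep)))
}

#' Exclude records with missing hospital outcome
#'
#' @param cohort Cohort data frame.
#' @return List with `cohort` and `report`.
#' @export
exclude_missing_outcome <- function(cohort) {
  require_columns(cohort, "hospital_outcome")
  n0 <- nrow(cohort)
  y <- outcome_binary(cohort)
  keep <- !is.na(y)
  list(cohort = cohort[keep, , drop = FALSE],
       report = new_filter_report("missing_outcome", n0, sum(!keep)))
}

#' Random train/validation split
#'
#' Simple random sampling without stratification; the training size is
#' `round(fraction * n)` (round-half-even). Reproducible under `seed`.
#'
#' @param cohort Cohort data frame with a `row_id` column (added if absent).
#' @param fraction Training fraction in (0, 1); default 0.85.
#' @param seed Integer seed.
#' @return Object of class `split_result`: list with `train_ids`,
#'   `validation_ids`, `fraction`, `seed`.
#' @export
split_train_validation <- function(cohort, fraction = 0.85, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_field("fraction", "must be in (0, 1)")
  }
  n <- nrow(cohort)
  if (n < 2) stop("cohort must have at least 2 records to split",
                  call. = FALSE)
  ids <- cohort$row_id %||% seq_len(n)
  n_train <- round(fraction * n)
  train <- withr::with_seed(seed, sort(sample(ids, n_train)))
  structure(list(train_ids = train,
                 validation_ids = sort(setdiff(ids, train)),
                 fraction = fraction, seed = seed),
            class = "split_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Cohort filter report\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Chain filter reports into a single flowchart table
#'
#' Validates the conservation invariant (records out of one step equal
#' records into the next) and returns one table covering all steps.
#'
#' @param reports List of `filter_report` objects, in application order.
#' @return A `filter_report` with all steps.
#' @export
flowchart_report <- function(reports) {
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  if (nrow(tab) > 1) {
    chained <- tab$n_out[-nrow(tab)] == tab$n_in[-1]
    if (!all(chained)) {
      stop("internal error: filter counts do not chain (conservation breach)",
           call. = FALSE)
    }
  }
  if (any(tab$n_in != tab$n_excluded + tab$n_out)) {
    stop("internal error: in != excluded + out in filter report",
         call. = FALSE)
  }
  class(tab) <- c("filter_report", "data.frame")
  tab
}

#' Write a flowchart report as JSON
#'
#' @param report A `filter_report`.
#' @param path File path.
#' @export
write_flowchart_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
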