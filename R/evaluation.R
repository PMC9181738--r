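#' ROC analysis: area under the curve by Mann-Whitney concordance
#'
#' The AUC is the probability that a randomly chosen death received a
#' higher predicted probability than a randomly chosen survivor, with tied
#' pairs counted 1/2 — computed from rank sums, which is exactly the
#' pairwise concordance.
#'
#' @param probabilities Predicted death probabilities (any monotone score
#'   works).
#' @param outcomes Binary outcome: 0/1, logical, or `alive`/`dead` strings.
#' @return Object of class `roc_result`: `auc`, `curve` (data frame of
#'   FPR/TPR at every threshold), `n_events`, `n_nonevents`.
#' @export
roc_auc <- function(probabilities, outcomes) {
  y <- if (is.character(outcomes)) {
    ifelse(outcomes == "dead", 1L, ifelse(outcomes == "alive", 0L,
                                          NA_integer_))
  } else as.integer(outcomes)
  ok <- !is.na(y) & !is.na(probabilities)
  y <- y[ok]; p <- probabilities[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  r <- rank(p)  # midranks: ties counted 1/2
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(p), decreasing = TRUE)
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  cum_tp <- cumsum(ys); cum_fp <- cumsum(1 - ys)
  last <- !duplicated(ps, fromLast = TRUE)
  curve <- data.frame(
    threshold = c(Inf, ps[last]),
    fpr = c(0, cum_fp[last] / n0),
    tpr = c(0, cum_tp[last] / n1)
  )
  structure(list(auc = auc, curve = curve, n_events = n1,
                 n_nonevents = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result AUC=%.3f (%d events / %d non-events)>\n",
              x$auc, x$n_events, x$n_nonevents))
  invisible(x)
}

#' Descriptive comparison table by hospital outcome
#'
#' Per variable: median (Q1, Q3) for continuous variables with a
#' Wilcoxon-Mann-Whitney p-value, count (%) per level for categorical and
#' binary variables with a chi-squared p-value (without continuity
#' correction by default, as customary for large registries). Percentages
#' are always recomputed from the counts and rounded to one decimal.
#' Missing values are reported as their own row, outside the percentages.
#'
#' @param cohort Cohort data frame with a `hospital_outcome` column.
#' @param variables Column names to describe; defaults to the pre-operative
#'   candidate dictionary plus the post-operative severity variables that
#'   are present.
#' @param continuity_correction Passed to [stats::chisq.test()] (default
#'   `FALSE`).
#' @return Data frame of class `cohort_description` with columns
#'   `variable`, `level`, `total`, `alive`, `dead`, `p_value` (the p-value
#'   is attached to the variable's first row, `NA` elsewhere; a constant
#'   column gets `NA` — not applicable).
#' @export
describe_cohort <- function(cohort, variables = NULL,
                            continuity_correction = FALSE) {
  require_columns(cohort, "hospital_outcome")
  y <- outcome_binary(cohort)
  grp <- ifelse(is.na(y), NA, ifelse(y == 1, "dead", "alive"))
  if (is.null(variables)) {
    dict <- rbind(candidate_dictionary("pre"), candidate_dictionary("post"))
    variables <- intersect(dict$variable, names(cohort))
  }
  fmt_num <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.3g (%.3g, %.3g)", q[1], q[2], q[3])
  }
  fmt_cnt <- function(k, n) {
    sprintf("%d (%.1f%%)", k, proportion_pct(k, max(n, 1)))
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (v in variables) {
    x <- cohort[[v]]
    miss <- is.na(x)
    xa <- x[!miss & grp == "alive"]; xd <- x[!miss & grp == "dead"]
    if (is.numeric(x)) {
      p <- if (length(unique(x[!miss])) < 2 || !length(xa) || !length(xd)) {
        NA_real_
      } else {
        suppressWarnings(stats::wilcox.test(xa, xd)$p.value)
      }
      add(variable = v, level = "median (Q1, Q3)",
          total = fmt_num(x[!miss]), alive = fmt_num(xa),
          dead = fmt_num(xd), p_value = p)
    } else {
      x <- as.character(x)
      lev <- if (is.logical(cohort[[v]])) "TRUE" else
        names(sort(table(x[!miss]), decreasing = TRUE))
      orders <- synthetic_level_orders()
      if (v %in% names(orders)) lev <- intersect(orders[[v]], unique(x[!miss]))
      tab <- table(factor(x[!miss], levels = lev),
                   factor(grp[!miss], levels = c("alive", "dead")))
      p <- if (length(lev) < 2 && !is.logical(cohort[[v]])) NA_real_ else {
        full <- if (is.logical(cohort[[v]])) {
          table(factor(x[!miss], levels = c("FALSE", "TRUE")),
                factor(grp[!miss], levels = c("alive", "dead")))
        } else tab
        if (any(dim(full) < 2) || any(rowSums(full) == 0) ||
            any(colSums(full) == 0)) NA_real_ else {
          suppressWarnings(stats::chisq.test(
            full, correct = continuity_correction)$p.value)
        }
      }
      n_tot <- sum(!miss & !is.na(grp))
      n_a <- sum(grp == "alive" & !miss, na.rm = TRUE)
      n_d <- sum(grp == "dead" & !miss, na.rm = TRUE)
      first <- TRUE
      for (l in lev) {
        add(variable = v, level = l,
            total = fmt_cnt(sum(x[!miss] == l, na.rm = TRUE), n_tot),
            alive = fmt_cnt(tab[l, "alive"], n_a),
            dead = fmt_cnt(tab[l, "dead"], n_d),
            p_value = if (first) p else NA_real_)
        first <- FALSE
      }
    }
    if (any(miss)) {
      add(variable = v, level = "missing",
          total = as.character(sum(miss)),
          alive = as.character(sum(miss & grp == "alive", na.rm = TRUE)),
          dead = as.character(sum(miss & grp == "dead", na.rm = TRUE)),
          p_value = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_description", "data.frame")
  out
}
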