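#' Model terms for risk model design matrices
#'
#' A risk model is defined by a list of terms, each describing how one
#' cohort column enters the linear predictor: as a plain linear effect, a
#' continuous piecewise-linear (linear spline) effect, or a categorical
#' effect with possibly merged levels. Terms are data, so a fitted model's
#' structure can be serialised, refitted on resampled data, and audited.
#'
#' @param name Column name in the cohort.
#' @return An object of class `risk_term`.
#' @name risk_terms
NULL

#' @rdname risk_terms
#' @export
term_linear <- function(name) {
  structure(list(name = name, type = "linear"), class = "risk_term")
}

#' @rdname risk_terms
#' @param knots Increasing numeric vector of knot locations, in the
#'   variable's units. `numeric(0)` collapses to a plain linear term.
#' @export
term_piecewise <- function(name, knots) {
  knots <- as.numeric(knots)
  if (length(knots) && any(diff(knots) <= 0)) {
    stop_field("knots", "must be strictly increasing")
  }
  if (!length(knots)) return(term_linear(name))
  structure(list(name = name, type = "piecewise", knots = knots),
            class = "risk_term")
}

#' @rdname risk_terms
#' @param levels Level labels in clinical order; first level is the
#'   reference. If `NULL`, taken from the data at design time.
#' @param levels_map Optional named character vector mapping original levels
#'   to (possibly merged) coded levels, e.g. `c(II = "II-III", III = "II-III")`.
#' @export
term_categorical <- function(name, levels = NULL, levels_map = NULL) {
  structure(list(name = name, type = "categorical", levels = levels,
                 levels_map = levels_map),
            class = "risk_term")
}

#' @rdname risk_terms
#' @export
term_binary <- function(name) {
  structure(list(name = name, type = "binary"), class = "risk_term")
}

#' @export
print.risk_term <- function(x, ...) {
  extra <- switch(x$type,
    piecewise = sprintf(" knots=[%s]", paste(x$knots, collapse = ", ")),
    categorical = if (!is.null(x$levels_map)) {
      sprintf(" levels=%s", paste(unique(x$levels_map), collapse = "|"))
    } else "",
    "")
  cat(sprintf("<risk_term %s: %s%s>\n", x$type, x$name, extra %||% ""))
  invisible(x)
}

# Coded levels of a categorical term, in clinical order.
term_coded_levels <- function(term, data) {
  lev <- term$levels
  if (is.null(lev)) {
    x <- data[[term$name]]
    lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  }
  if (is.null(term$levels_map)) return(lev)
  unique(unname(term$levels_map[lev]))
}

# Design columns contributed by one term (no intercept column).
term_columns <- function(term, data) {
  nm <- term$name
  if (!nm %in% names(data)) {
    stop(sprintf("required column `%s` is missing", nm), call. = FALSE)
  }
  x <- data[[nm]]
  switch(term$type,
    linear = {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- nm
      m
    },
    binary = {
      m <- matrix(as.numeric(as.logical(x)), ncol = 1)
      colnames(m) <- nm
      m
    },
    piecewise = {
      x <- as.numeric(x)
      m <- cbind(x, vapply(term$knots, function(k) pmax(x - k, 0),
                           numeric(length(x))))
      colnames(m) <- c(nm, sprintf("%s_gt%g", nm, term$knots))
      m
    },
    categorical = {
      x <- as.character(x)
      if (!is.null(term$levels_map)) {
        unknown <- setdiff(unique(x[!is.na(x)]), names(term$levels_map))
        if (length(unknown)) {
          stop(sprintf("column `%s` has level(s) not in levels_map: %s",
                       nm, paste(unknown, collapse = ", ")), call. = FALSE)
        }
        x <- unname(term$levels_map[x])
      }
      lev <- term_coded_levels(term, data)
      f <- factor(x, levels = lev)
      m <- vapply(lev[-1], function(l) as.numeric(f == l),
                  numeric(length(f)))
      m <- matrix(m, ncol = length(lev) - 1)
      colnames(m) <- sprintf("%s=%s", nm, lev[-1])
      # propagate NA for unseen values
      m[is.na(f), ] <- NA_real_
      m
    },
    stop(sprintf("unknown term type `%s`", term$type), call. = FALSE)
  )
}

#' Build a design matrix (with intercept) from a term list
#'
#' @param data Cohort data frame.
#' @param terms List of `risk_term` objects.
#' @return Numeric matrix with an `(Intercept)` column first.
#' @export
build_design <- function(data, terms) {
  stopifnot(is.list(terms))
  cols <- lapply(terms, term_columns, data = data)
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(data))), cols))
  colnames(X)[1] <- "(Intercept)"
  X
}

term_names <- function(terms) vapply(terms, `[[`, character(1), "name")
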