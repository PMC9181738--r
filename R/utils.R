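#' dualbench: paired pre/post-operative risk models and center benchmarking
#'
#' Tools to develop paired pre-operative and post-operative logistic models
#' for in-hospital mortality after cardiac surgery, and to benchmark centers
#' and patient subgroups through the relative difference in expected deaths
#' `d = (e_post - e_pre) / e_pre` with percentile bootstrap confidence
#' intervals. A synthetic multi-center cohort generator with known ground
#' truth supports offline validation of every stage.
#'
#' @keywords internal
#' @useDynLib dualbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of a count, rounded to printed precision
#'
#' Recomputes a proportion as a percentage rounded to a fixed number of
#' decimals, the convention used in descriptive cohort tables.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage, e.g. `proportion_pct(562, 15533)` is `3.6`.
#' @export
proportion_pct <- function(count, total, digits = 1) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  round(100 * count / total, digits)
}

# Derive a per-stage seed from a root seed so every stage draws from its own
# named substream. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, filter = 211L, split = 307L, fit = 401L,
               evaluate = 503L, benchmark = 601L, experiment = 701L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483629)
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue method
# (physicists' convention). Used to marginalise logistic probabilities
# over a normal random effect without Monte Carlo error.
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

# E[plogis(lp + sigma * Z)] with Z ~ N(0,1), vectorised over lp.
logistic_normal_marginal <- function(lp, sigma, k = 21) {
  if (sigma == 0) return(stats::plogis(lp))
  gh <- gauss_hermite(k)
  z <- sqrt(2) * gh$nodes
  w <- gh$weights / sqrt(pi)
  out <- numeric(length(lp))
  for (j in seq_len(k)) out <- out + w[j] * stats::plogis(lp + sigma * z[j])
  out
}

# Tiny FNV-1a hash of a character string, for run manifests.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Binary outcome from the cohort's hospital_outcome column.
# "missing" (or NA) maps to NA; callers decide whether that is an error.
outcome_binary <- function(cohort, column = "hospital_outcome") {
  if (!column %in% names(cohort)) {
    stop(sprintf("required column `%s` is missing", column), call. = FALSE)
  }
  x <- cohort[[column]]
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) return(as.integer(x))
  y <- ifelse(x == "dead", 1L, ifelse(x == "alive", 0L, NA_integer_))
  y
}
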