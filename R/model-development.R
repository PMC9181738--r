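#' Model development protocol configuration
#'
#' Thresholds of the development protocol: rare-variable exclusion
#' (subgroups with fewer than `min_patients` records or `min_events`
#' deaths), bivariate screening (discard if p > `p_screen`), stepwise
#' selection (enter/retain at p < `p_select`), the linearity gate for
#' piecewise transforms, and the level-merging contrast threshold.
#'
#' @param min_patients Minimum subgroup size (default 100).
#' @param min_events Minimum deaths in the subgroup (default 30).
#' @param p_screen Bivariate screening threshold (default 0.25).
#' @param p_select Stepwise selection threshold (default 0.01).
#' @param max_knots Maximum knots for piecewise-linear transforms (default 2).
#' @param level_merge_p Wald threshold above which adjacent categorical
#'   levels are merged (default 0.05).
#' @param linearity_alpha Significance of the likelihood-ratio linearity
#'   test, after multiplicity adjustment for the knot search (default 0.05).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(min_patients = 100, min_events = 30,
                             p_screen = 0.25, p_select = 0.01,
                             max_knots = 2, level_merge_p = 0.05,
                             linearity_alpha = 0.05) {
  if (!(p_select > 0 && p_select < p_screen && p_screen < 1)) {
    stop_field("p_select/p_screen", "need 0 < p_select < p_screen < 1")
  }
  if (min_patients < 1 || min_events < 1 || max_knots < 0) {
    stop_field("counts", "must be positive")
  }
  structure(list(min_patients = min_patients, min_events = min_events,
                 p_screen = p_screen, p_select = p_select,
                 max_knots = max_knots, level_merge_p = level_merge_p,
                 linearity_alpha = linearity_alpha),
            class = "selection_config")
}

# Clinical level orders for the synthetic cohort's categorical columns;
# first level is the reference.
synthetic_level_orders <- function() {
  list(sex = c("female", "male"),
       nyha = c("I", "II", "III", "IV"),
       ef_class = c(">50", "30-50", "<30"),
       urgency = c("elective", "deferred", "emergent", "salvage"))
}

#' Turn a variable dictionary into candidate terms
#'
#' Continuous variables start as linear terms (piecewise transforms are
#' decided later), categorical variables carry their clinical level order
#' (most frequent level first when the order is unknown), binary flags are
#' 0/1 indicators.
#'
#' @param cohort Cohort data frame.
#' @param dictionary Data frame with `variable` and `type` columns, e.g.
#'   [candidate_dictionary()].
#' @return Named list of [risk_terms].
#' @export
candidate_terms <- function(cohort, dictionary) {
  orders <- synthetic_level_orders()
  out <- lapply(seq_len(nrow(dictionary)), function(i) {
    v <- dictionary$variable[i]
    switch(dictionary$type[i],
      continuous = term_linear(v),
      binary = term_binary(v),
      categorical = {
        obs <- table(as.character(cohort[[v]]))
        lev <- if (v %in% names(orders)) {
          intersect(orders[[v]], names(obs))
        } else {
          names(sort(obs, decreasing = TRUE))
        }
        term_categorical(v, levels = lev)
      },
      stop(sprintf("unknown candidate type `%s`", dictionary$type[i]),
           call. = FALSE))
  })
  stats::setNames(out, dictionary$variable)
}

#' Exclude variables representing rare events
#'
#' A binary variable is dropped when its exposed subgroup has fewer than
#' `min_patients` records or fewer than `min_events` deaths (strict "less
#' than": 100 patients with 30 events is kept). A rare level of a
#' categorical variable is merged into the preceding level in clinical
#' order (into the following one for the reference level); the variable is
#' dropped only if a single level remains. Continuous variables pass
#' through.
#'
#' @param cohort Cohort data frame (non-missing outcomes).
#' @param candidates Named list of [risk_terms].
#' @param config A [selection_config()].
#' @return List with `kept` (terms, rare levels pre-merged), `dropped`
#'   (variable names) and `table` (per-subgroup counts and status).
#' @export
screen_rare_variables <- function(cohort, candidates,
                                  config = selection_config()) {
  y <- outcome_binary(cohort)
  rows <- list(); kept <- list(); dropped <- character()
  for (nm in names(candidates)) {
    term <- candidates[[nm]]
    if (term$type %in% c("linear", "piecewise")) {
      kept[[nm]] <- term
      next
    }
    if (term$type == "binary") {
      exposed <- as.logical(cohort[[nm]])
      n <- sum(exposed, na.rm = TRUE)
      ev <- sum(y[exposed], na.rm = TRUE)
      ok <- n >= config$min_patients && ev >= config$min_events
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, level = "TRUE", n = n, events = ev,
        status = if (ok) "kept" else "dropped")
      if (ok) kept[[nm]] <- term else dropped <- c(dropped, nm)
      next
    }
    # categorical: merge rare levels into their clinical neighbour
    lev <- term_coded_levels(term, cohort)
    x <- as.character(cohort[[nm]])
    counts <- vapply(lev, function(l) sum(x == l, na.rm = TRUE), numeric(1))
    events <- vapply(lev, function(l) sum(y[x == l], na.rm = TRUE),
                     numeric(1))
    rare <- counts < config$min_patients | events < config$min_events
    for (j in seq_along(lev)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, level = lev[j], n = counts[j], events = events[j],
        status = if (rare[j]) "merged" else "kept")
    }
    map <- stats::setNames(lev, lev)
    if (length(lev) >= 2) {
      for (j in seq_along(lev)) {
        if (!rare[j]) next
        # absorb into the preceding clinical level (following one for the
        # reference level)
        map[lev[j]] <- if (j == 1) lev[2] else map[[lev[j - 1]]]
      }
      if (rare[1] && length(lev) > 1) {
        # re-point in case level 2 itself was absorbed elsewhere
        map[lev[1]] <- map[[lev[2]]]
      }
    }
    new_lev <- unique(unname(map[lev]))
    if (length(new_lev) < 2) {
      dropped <- c(dropped, nm)
    } else {
      kept[[nm]] <- term_categorical(nm, levels = term$levels %||% lev,
                                     levels_map = if (any(rare)) map)
    }
  }
  list(kept = kept, dropped = dropped,
       table = do.call(rbind, rows) %||% data.frame())
}

#' Bivariate screening against outcome
#'
#' Single-covariate logistic fit per candidate; the likelihood-ratio
#' p-value against the intercept-only model is compared to `p_screen`
#' (keep if p <= 0.25 by default). Fits with (quasi-)separation are
#' flagged and kept for review rather than discarded.
#'
#' @inheritParams screen_rare_variables
#' @return Data frame with `variable`, `df`, `p_value`, `separation`,
#'   `kept`.
#' @export
bivariate_screen <- function(cohort, candidates,
                             config = selection_config()) {
  y_all <- outcome_binary(cohort)
  rows <- lapply(names(candidates), function(nm) {
    term <- candidates[[nm]]
    cols <- term_columns(term, cohort)
    ok <- stats::complete.cases(cols) & !is.na(y_all)
    X <- cbind(`(Intercept)` = 1, cols[ok, , drop = FALSE])
    y <- y_all[ok]
    fit <- tryCatch(fit_logistic(X, y, allow_separation = TRUE),
                    error = function(e) NULL)
    null <- fit_logistic(matrix(1, sum(ok), 1,
                                dimnames = list(NULL, "(Intercept)")), y)
    if (is.null(fit)) {
      return(data.frame(variable = nm, df = ncol(X) - 1, p_value = NA_real_,
                        separation = TRUE, kept = TRUE))
    }
    p <- lrt_pvalue(null, fit, df = ncol(X) - 1)
    sep <- fit$separation
    data.frame(variable = nm, df = ncol(X) - 1,
               p_value = if (sep) NA_real_ else p,
               separation = sep,
               kept = sep || p <= config$p_screen)
  })
  do.call(rbind, rows)
}

#' Test linearity of the logit and fit a piecewise-linear transform
#'
#' Candidate knots sit at the deciles of the variable; the best single-knot
#' and best two-knot linear-spline fits are chosen by AIC, and the better
#' of the two is kept only when its likelihood-ratio test against the plain
#' linear fit rejects at `linearity_alpha` after Bonferroni adjustment for
#' the number of knot configurations searched (the adjustment keeps the
#' knot search from inflating the linearity test's size). Otherwise the
#' transform has zero knots.
#'
#' @param cohort Cohort data frame (non-missing outcomes).
#' @param variable Continuous column name.
#' @param config A [selection_config()].
#' @return Object of class `piecewise_transform`: `variable`, `knots`
#'   (possibly empty), `slopes` (per segment, log-odds per unit),
#'   `p_linearity`, and the corresponding `term`.
#' @export
fit_piecewise <- function(cohort, variable, config = selection_config()) {
  y_all <- outcome_binary(cohort)
  x_all <- as.numeric(cohort[[variable]])
  ok <- !is.na(x_all) & !is.na(y_all)
  x <- x_all[ok]; y <- y_all[ok]
  if (length(unique(x)) < 2) {
    stop(sprintf("`%s` is constant; cannot assess linearity", variable),
         call. = FALSE)
  }
  lin <- fit_logistic(cbind(`(Intercept)` = 1, x = x), y)
  cand <- unique(stats::quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE))
  cand <- cand[cand > min(x) & cand < max(x)]
  fit_knots <- function(knots) {
    X <- cbind(1, x, vapply(knots, function(k) pmax(x - k, 0),
                            numeric(length(x))))
    tryCatch(fit_logistic(X, y), error = function(e) NULL)
  }
  best <- NULL; n_searched <- 0
  for (nk in seq_len(min(config$max_knots, 2))) {
    sets <- if (nk == 1) as.list(cand) else {
      if (length(cand) < 2) list() else
        utils::combn(cand, 2, simplify = FALSE)
    }
    for (ks in sets) {
      n_searched <- n_searched + 1
      f <- fit_knots(ks)
      if (is.null(f)) next
      aic <- f$deviance + 2 * length(f$coefficients)
      if (is.null(best) || aic < best$aic) {
        best <- list(fit = f, knots = as.numeric(ks), aic = aic)
      }
    }
  }
  linear_out <- function(p) {
    structure(list(variable = variable, knots = numeric(0),
                   slopes = unname(lin$coefficients[2]),
                   p_linearity = p, term = term_linear(variable)),
              class = "piecewise_transform")
  }
  if (is.null(best)) return(linear_out(1))
  stat <- lin$deviance - best$fit$deviance
  p_adj <- min(1, stats::pchisq(stat, df = length(best$knots),
                                lower.tail = FALSE) * n_searched)
  if (p_adj >= config$linearity_alpha) return(linear_out(p_adj))
  b <- unname(best$fit$coefficients)
  slopes <- cumsum(b[-1])
  structure(list(variable = variable, knots = best$knots, slopes = slopes,
                 p_linearity = p_adj,
                 term = term_piecewise(variable, best$knots)),
            class = "piecewise_transform")
}

#' @export
print.piecewise_transform <- function(x, ...) {
  if (length(x$knots)) {
    cat(sprintf("<piecewise %s: knots [%s], slopes [%s], p=%.3g>\n",
                x$variable, paste(signif(x$knots, 4), collapse = ", "),
                paste(signif(x$slopes, 3), collapse = ", "), x$p_linearity))
  } else {
    cat(sprintf("<linear %s: slope %.3g (linearity not rejected, p=%.3g)>\n",
                x$variable, x$slopes[1], x$p_linearity))
  }
  invisible(x)
}

#' Forward/backward stepwise selection by likelihood-ratio tests
#'
#' Alternates forward entry (smallest LRT p-value among candidates, entered
#' if p < `p_select`; ties broken by smallest p then lexical name) with
#' backward elimination (largest LRT p-value among removable terms, removed
#' if p >= `p_select`) until stable. Terms in `forced` are never removed.
#' All fits use the common complete-case set over every candidate so that
#' likelihoods are comparable. Deterministic given the data and config; an
#' oscillation beyond 20 cycles is an error naming the cycling terms.
#'
#' @param cohort Cohort data frame (non-missing outcomes).
#' @param candidates Named list of [risk_terms].
#' @param config A [selection_config()].
#' @param forced List of terms always retained (e.g. the pre-operative
#'   model's terms when building the post-operative model).
#' @param stage `"pre"` or `"post"`.
#' @return A `risk_model` whose `$selected` names the terms added by
#'   selection and `$forced` the forced ones.
#' @export
stepwise_select <- function(cohort, candidates,
                            config = selection_config(), forced = list(),
                            stage = c("pre", "post")) {
  stage <- match.arg(stage)
  all_terms <- c(forced, candidates)
  y_all <- outcome_binary(cohort)
  cols <- lapply(all_terms, term_columns, data = cohort)
  ok <- !is.na(y_all)
  for (m in cols) ok <- ok & stats::complete.cases(m)
  dat <- cohort[ok, , drop = FALSE]
  y <- y_all[ok]
  fit_terms <- function(terms) {
    X <- build_design(dat, terms)
    tryCatch(fit_logistic(X, y, allow_separation = TRUE),
             error = function(e) NULL)
  }
  forced_names <- if (length(forced)) term_names(forced) else character()
  active <- if (length(forced)) stats::setNames(forced, forced_names) else list()
  if (is.null(names(candidates)) && length(candidates)) {
    candidates <- stats::setNames(candidates, term_names(candidates))
  }
  pool <- candidates[setdiff(names(candidates), forced_names)]
  f_act <- fit_terms(active)
  if (is.null(f_act)) stop("forced model cannot be fitted", call. = FALSE)

  changed_last <- TRUE
  for (cycle in seq_len(20)) {
    changed <- FALSE
    if (length(pool)) {
      ps <- vapply(names(pool), function(nm) {
        f <- fit_terms(c(active, pool[nm]))
        if (is.null(f) || f$separation) return(NA_real_)
        lrt_pvalue(f_act, f)
      }, numeric(1))
      cand_order <- order(ps, names(pool), na.last = TRUE)
      best <- cand_order[1]
      if (!is.na(ps[best]) && ps[best] < config$p_select) {
        nm <- names(pool)[best]
        active <- c(active, pool[nm])
        pool <- pool[setdiff(names(pool), nm)]
        f_act <- fit_terms(active)
        changed <- TRUE
      }
    }
    repeat {
      removable <- setdiff(names(active), forced_names)
      if (!length(removable)) break
      ps <- vapply(removable, function(nm) {
        f <- fit_terms(active[setdiff(names(active), nm)])
        if (is.null(f)) return(NA_real_)
        lrt_pvalue(f, f_act)
      }, numeric(1))
      worst <- order(-ps, removable)[1]
      if (!is.na(ps[worst]) && ps[worst] >= config$p_select) {
        nm <- removable[worst]
        pool[nm] <- active[nm]
        active <- active[setdiff(names(active), nm)]
        f_act <- fit_terms(active)
        changed <- TRUE
      } else break
    }
    changed_last <- changed
    if (!changed) break
  }
  if (changed_last) {
    stop(sprintf("stepwise selection did not stabilise in 20 cycles; active: %s",
                 paste(names(active), collapse = ", ")), call. = FALSE)
  }
  model <- structure(list(
    stage = stage, terms = unname(active),
    coefficients = f_act$coefficients, vcov = f_act$vcov,
    deviance = f_act$deviance, null_deviance = f_act$null_deviance,
    converged = f_act$converged, n = length(y),
    n_dropped_incomplete = sum(!ok), events = sum(y),
    selected = unname(setdiff(names(active), forced_names)),
    forced = unname(forced_names)
  ), class = "risk_model")
  model
}

#' Merge statistically indistinguishable categorical levels
#'
#' Levels of `variable` (at least 3 in the current model) are ordered by
#' their estimated odds ratios; the adjacent pair with the largest Wald
#' p-value for the pairwise contrast is merged when that p-value is at
#' least `level_merge_p` and the pair is allowed by the clinical grouping
#' configuration, then the model is refitted. Repeats until no merge
#' applies.
#'
#' @param model A fitted `risk_model` containing a categorical term for
#'   `variable`.
#' @param cohort The cohort the model was fitted on.
#' @param variable Categorical variable name.
#' @param config A [selection_config()].
#' @param allowed_groups Optional list of character vectors of original
#'   levels; a merge is allowed only within one group. `NULL` allows all
#'   merges (clinical reasoning unconstrained).
#' @return The refitted `risk_model` (unchanged if the variable has fewer
#'   than 3 levels or no merge is supported).
#' @export
merge_levels <- function(model, cohort, variable,
                         config = selection_config(),
                         allowed_groups = NULL) {
  idx <- which(term_names(model$terms) == variable)
  if (!length(idx)) stop(sprintf("`%s` is not in the model", variable),
                         call. = FALSE)
  term <- model$terms[[idx[1]]]
  if (term$type != "categorical") {
    stop(sprintf("`%s` is not categorical", variable), call. = FALSE)
  }
  repeat {
    lev <- term_coded_levels(term, cohort)
    if (length(lev) < 3) break
    cf <- stats::setNames(rep(0, length(lev)), lev)
    vnames <- sprintf("%s=%s", variable, lev[-1])
    cf[lev[-1]] <- model$coefficients[vnames]
    V <- model$vcov
    ord <- order(cf)
    pair_p <- function(l1, l2) {
      v1 <- sprintf("%s=%s", variable, l1)
      v2 <- sprintf("%s=%s", variable, l2)
      var1 <- if (v1 %in% rownames(V)) V[v1, v1] else 0
      var2 <- if (v2 %in% rownames(V)) V[v2, v2] else 0
      cov12 <- if (v1 %in% rownames(V) && v2 %in% rownames(V)) V[v1, v2] else 0
      se <- sqrt(var1 + var2 - 2 * cov12)
      if (!is.finite(se) || se == 0) return(0)
      2 * stats::pnorm(-abs(cf[l1] - cf[l2]) / se)
    }
    orig_of <- function(coded) {
      map <- term$levels_map
      if (is.null(map)) coded else names(map)[map == coded]
    }
    allowed <- function(l1, l2) {
      if (is.null(allowed_groups)) return(TRUE)
      orig <- c(orig_of(l1), orig_of(l2))
      any(vapply(allowed_groups, function(g) all(orig %in% g), logical(1)))
    }
    best_p <- -1; best_pair <- NULL
    for (j in seq_len(length(lev) - 1)) {
      l1 <- lev[ord[j]]; l2 <- lev[ord[j + 1]]
      if (!allowed(l1, l2)) next
      p <- pair_p(l1, l2)
      if (p > best_p) { best_p <- p; best_pair <- c(l1, l2) }
    }
    if (is.null(best_pair) || best_p < config$level_merge_p) break
    # merge: keep clinical order, label by constituent coded labels
    pos <- sort(match(best_pair, lev))
    new_label <- paste(lev[pos], collapse = "-")
    map <- term$levels_map %||%
      stats::setNames(term$levels %||% lev, term$levels %||% lev)
    map[map %in% best_pair] <- new_label
    term <- term_categorical(variable, levels = term$levels %||% names(map),
                             levels_map = map)
    model$terms[[idx[1]]] <- term
    model <- fit_risk_model(cohort, model$terms, stage = model$stage)
    model$terms[[idx[1]]] <- term
  }
  model
}

#' Build the post-operative model with forced pre-operative terms
#'
#' Stepwise selection over the post-operative candidates with every term of
#' the pre-operative model in the forced list — pre-operative terms stay in
#' the post-operative model regardless of their statistical significance.
#' Coefficients are re-estimated from scratch, never carried over.
#'
#' @param cohort Cohort data frame (training set).
#' @param preop_model The fitted pre-operative `risk_model`.
#' @param postop_candidates Named list of post-operative candidate terms.
#' @param config A [selection_config()].
#' @return The post-operative `risk_model`; its term set is a superset of
#'   the pre-operative one.
#' @export
build_postop_model <- function(cohort, preop_model, postop_candidates,
                               config = selection_config()) {
  forced <- stats::setNames(preop_model$terms, term_names(preop_model$terms))
  stepwise_select(cohort, postop_candidates, config, forced = forced,
                  stage = "post")
}

#' Run the full development protocol for one model stage
#'
#' Rare-variable screening, bivariate screening, linearity testing with
#' piecewise replacement for continuous variables, forward/backward
#' stepwise selection, then level merging for categorical variables left in
#' the model.
#'
#' @param train Training cohort (non-missing outcomes).
#' @param dictionary Candidate dictionary (see [candidate_dictionary()]).
#' @param config A [selection_config()].
#' @param forced List of terms forced into the model.
#' @param stage `"pre"` or `"post"`.
#' @param allowed_groups Clinical grouping constraint for [merge_levels()].
#' @return A `risk_model` with a `$protocol` element recording the
#'   screening tables and transforms.
#' @export
develop_risk_model <- function(train, dictionary,
                               config = selection_config(),
                               forced = list(),
                               stage = c("pre", "post"),
                               allowed_groups = NULL) {
  stage <- match.arg(stage)
  cands <- candidate_terms(train, dictionary)
  rare <- screen_rare_variables(train, cands, config)
  biv <- bivariate_screen(train, rare$kept, config)
  keep_names <- biv$variable[biv$kept]
  cands2 <- rare$kept[keep_names]
  transforms <- list()
  for (nm in names(cands2)) {
    if (cands2[[nm]]$type == "linear") {
      tr <- fit_piecewise(train, nm, config)
      transforms[[nm]] <- tr
      cands2[[nm]] <- tr$term
    }
  }
  model <- stepwise_select(train, cands2, config, forced = forced,
                           stage = stage)
  for (nm in term_names(model$terms)) {
    tm <- model$terms[[which(term_names(model$terms) == nm)[1]]]
    if (tm$type == "categorical" &&
        length(term_coded_levels(tm, train)) >= 3) {
      model <- merge_levels(model, train, nm, config, allowed_groups)
    }
  }
  model$protocol <- list(rare = rare$table, rare_dropped = rare$dropped,
                         bivariate = biv, transforms = transforms)
  model
}
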