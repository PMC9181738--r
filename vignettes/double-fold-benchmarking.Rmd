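---
title: "Benchmarking intraoperative performance with paired pre/post-operative risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking intraoperative performance with paired pre/post-operative risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Perioperative risk scores for cardiac surgery (EuroSCORE-family,
STS, ACEF) are built on pre-operative information only, so they cannot
separate what the patient brought into the operating theatre from what
happened inside it. `dualbench` implements a *double-fold* alternative:
two logistic regression models for in-hospital death are developed on the
same cohort —

* a **pre-operative model**, using only variables available at operating
  theatre admission (demographics, comorbidities, NYHA class, ejection
  fraction, renal function, urgency, procedure type), and
* a **post-operative model**, which additionally uses the patient's state
  at ICU admission, immediately after surgery, and is forced to contain
  every term of the pre-operative model regardless of significance.

For any group of patients (a center, or a center × subgroup cell), the
expected deaths under each model are the sums of predicted probabilities,
$e_{\mathrm{pre}} = \sum_i \hat p^{\mathrm{pre}}_i$ and
$e_{\mathrm{post}} = \sum_i \hat p^{\mathrm{post}}_i$, and intraoperative
performance is summarised by the relative difference

$$d = \frac{e_{\mathrm{post}} - e_{\mathrm{pre}}}{e_{\mathrm{pre}}}.$$

A positive $d$ means patients left the theatre with more predicted risk
than they entered with, once case-mix is accounted for; a negative $d$
means the opposite. Because both models are developed on the pooled
multi-center cohort, $d$ is implicitly measured *relative to the average
intraoperative performance of the participating centers*: a center can
only look good or bad compared to its peers, not to an absolute standard.
Uncertainty in $d$ is quantified by a percentile bootstrap: the whole
cohort is resampled with replacement, both models are re-estimated on
each replicate (fixed term structure, coefficients refitted from
scratch), and $d$ is recomputed per unit from the resampled records; the
95% interval is the 2.5th–97.5th percentile across replicates.

## The development protocol

Model development follows a fixed, auditable protocol
(`develop_risk_model()`), with every threshold exposed in
`selection_config()`:

1. **Rare-variable screening** — a binary variable (or categorical level)
   whose exposed subgroup has fewer than 100 patients or fewer than 30
   deaths is excluded (rare levels are merged into their clinical
   neighbour). Both bounds are strict "less than": 100 patients with 30
   events survives.
2. **Bivariate screening** — each surviving candidate is fitted alone
   against outcome; candidates with a likelihood-ratio p-value above 0.25
   are discarded. Fits with (quasi-)separation are flagged and kept for
   review rather than silently dropped.
3. **Linearity testing** — for each continuous variable the logit is
   allowed to bend: candidate knots sit at the deciles, the best one- and
   two-knot linear splines are chosen by AIC, and the winner replaces the
   linear term only when its likelihood-ratio test against linearity
   rejects at 0.05 *after Bonferroni adjustment for the number of knot
   configurations searched*. Without that adjustment the best-of-search
   statistic would reject linearity far above the nominal rate; with it,
   a genuinely linear effect stays linear and a hinge-shaped effect of,
   say, creatinine clearance is recovered with its knot.
4. **Stepwise selection** — alternating forward entry (smallest LRT
   p-value, entered if p < 0.01; ties broken by p then lexical name) and
   backward elimination (removed if p ≥ 0.01), until stable, with a
   20-cycle cap that errors rather than loops. All candidate fits share
   one complete-case set so likelihoods are comparable. All selection
   tests are likelihood-ratio tests: they remain well defined under
   forced terms and near-separated fits, where Wald statistics degrade.
5. **Level merging** — levels of a categorical variable left in the model
   are ordered by estimated odds ratio and adjacent pairs are merged while
   the pairwise Wald contrast has p ≥ 0.05 and the pair is allowed by an
   explicit clinical-grouping configuration, so "clinical reasoning" is an
   input one can inspect, not hidden code.
6. **Post-operative stage** — stepwise selection over the post-operative
   candidates with the entire pre-operative term list forced in.
   Coefficients are never transferred between stages; only structure is.

## Evaluation

Discrimination is the AUC, computed as the Mann–Whitney concordance with
tied pairs counted 1/2 (`roc_auc()`; it agrees exactly with exhaustive
pair counting, which the test suite verifies on every input up to 200
records). Calibration uses a polynomial-recalibration belt and test
(`calibration_belt()`): the logit of the predicted probability is
recalibrated with a polynomial whose degree grows while each increment's
LRT is significant at 0.05 (maximum degree 4), and the test statistic is
the deviance gap between the identity line and the selected polynomial.
Its p-value is computed from the *selection-conditional* null
distribution — a $\chi^2_2$ convolved with one truncated $\chi^2_1$ per
accepted increment — which keeps the p-value uniform under correct
calibration despite the data-driven degree. On a model's own development
data the degree-1 recalibration is exactly the identity by construction,
so the internal-evaluation variant (`devel = "internal"`) starts the
polynomial at degree 2 and replaces the base component with an
unconditioned $\chi^2_1$. The belt is a Scheffé-style confidence region
of the recalibration curve with quantiles taken from the same
conditional distribution.

## The synthetic cohort generator

The registry this methodology targets cannot be redistributed, so the
package ships a generator (`generate_cohort()`) whose defaults emulate a
contemporary adult cardiac-surgery registry: 20 centers × 800 admissions,
median age 70, ~68% male, ~84% elective surgery, NYHA and ejection-fraction
distributions typical of such cohorts, log-normal creatinine clearance,
and ~3.6% hospital mortality (the intercept is calibrated to that rate
under the default case-mix). Age and creatinine clearance enter the true
pre-operative logit piecewise-linearly (knots at 65 years and 65 mL/min),
the shapes the fitted models are expected to rediscover.

Two design choices matter for interpreting the validation studies:

* **Center effects are mediated by observable severity.** Each center
  carries an intraoperative log-odds shift, but the post-operative model
  contains no center term — in real data a center's performance is
  visible only through the state its patients arrive in at the ICU. The
  generator therefore routes the shift through the means of two
  observable ICU-admission severity variables; the patient-level
  intraoperative contribution has standard deviation `postop_noise_sd`
  (default 0.5 log-odds). Had the shift been injected directly into the
  outcome instead, no post-operative model could ever detect it and $d$
  would be powerless by construction.
* **Ground truth is defined at the level an ideal model could reach.**
  The true post-operative probability is the generating probability. The
  true pre-operative probability is the *marginal* probability over the
  patient-level intraoperative contribution at the zero-shift
  (average-center) reference, computed by Gauss–Hermite quadrature. This
  is the estimand of an ideal pre-operative model; it makes true $d$
  exactly zero when shifts and noise are zero, and one center's shift
  never moves another center's truth. Default shifts span ±0.45
  log-odds, centered on zero, matching the spread of relative differences
  such registries report.

The generator also produces the messiness the cohort filters exist for:
re-admissions (duplicated patients with later timestamps), a small rate
of pediatric, pre-surgical-ICU and Type-B dissection admissions,
(center, month) strata degraded with incomplete records, and missing
hospital outcomes (~2.2%, matching the proportion such registries lose).

What the generator does **not** emulate: the joint dependence structure
of real comorbidities (covariates are drawn independently), seasonal or
secular trends, within-surgeon clustering, and informative missingness —
incompleteness and missing outcomes are missing completely at random.
Passing validation studies therefore demonstrate that the machinery is
correct and well calibrated under a faithful-but-idealised data-generating
process, not that any particular real registry satisfies the models'
assumptions.

## Cohort filters

The exclusion cascade is fixed and reported as a flowchart table:
age (strictly over 16 retained) → Type-B dissection repair → ICU
admission before surgery → first admission only; then the month-level
completeness rule — every record of a (center, month) stratum is removed
when *strictly more than* 10% of the stratum's records are incomplete
(exactly 10% survives); then records with missing hospital outcome.
Completeness strata are per (center, month), not global months: one
center's bad month should not evict other centers' patients, since the
rule targets site-level data quality. The train/validation split is
simple random sampling of 85%/15% with `round()` (round-half-even)
arithmetic and no stratification.

## Numerical choices

* Logistic fits go through IRLS (`stats::glm.fit`) with deviance
  tolerance 1e-10 and 100 iterations; rank deficiency is an error naming
  the collinear columns; separation is judged by a collapsed deviance or
  a diverging coefficient *on the covariate's own scale* (|β|·sd > 15),
  so poorly conditioned but legitimate fits are not misflagged.
* Bootstrap refits use a warm-started Armadillo IRLS (`src/irls.cpp`)
  with the point estimates as starting values — the only compiled code in
  the package, justified by the ~2 × B refits per benchmarking call.
* Replicates where a unit has zero resampled `e_pre` contribute missing
  values; a CI is reported only when ≥ 80% of replicates are usable.
* All randomness descends from one root seed through named per-stage
  substreams; reruns are byte-identical.

## Validation studies and their sizes

The package validates itself with simulation studies whose problem sizes
were chosen once, as a balance between statistical resolution and the
cost of a routine test run:

* **Parameter recovery**: 100 replicate cohorts, each with a target
  center of 1000 patients whose true $d$ is ≈ 0.30 (shift calibrated to
  +0.296 log-odds) inside an 11-center cohort whose background shifts
  offset the target's so the cohort-weighted mean shift is zero; B = 500
  bootstrap replicates. The 95% CI must cover the generator truth in at
  least 90 of 100 runs.
* **Null coverage**: 20 cohorts × 8 centers with all shifts zero,
  B = 200; the fraction of 95% CIs containing zero must sit inside a
  three-sigma binomial band around 95%.
* **Calibration-test size**: 500 null simulations at n = 2000; the
  rejection rate at the 0.05 level must sit within three binomial
  standard errors of 5%.
* **Stepwise operating characteristics**: 100 cohorts of n = 5000 with
  one true log-OR-1 covariate among 10 independent noise covariates;
  the true covariate must be selected in ≥ 95 runs and per-variable noise
  inclusion must match the 1% gate within a binomial band.

These studies use a reduced case-mix (piecewise age, creatinine
clearance, urgency with the sparse salvage stratum pre-merged, as the
rare-variable screen would do at these sizes) so the many-replicate
studies stay cheap; the full default case-mix is exercised end-to-end by
the pipeline tests and the acceptance script.

## Known limitations

* $d$ compares centers to the cohort average, so adding or removing
  centers changes every center's reference point.
* The bootstrap re-estimates coefficients but not the variable selection
  itself (re-running stepwise selection inside each replicate is
  unstable and costly; the term structure is treated as fixed, a common
  and documented simplification).
* Logistic non-collapsibility means the pre-operative model's
  coefficients are mildly attenuated relative to the conditional
  generating values whenever unobserved intraoperative variation exists;
  center-level expected-death sums, which is all $d$ uses, are far less
  affected, and the recovery study quantifies the net effect.
* With `postop_noise_sd = 0` and non-zero shifts the generator's shift is
  unobservable by construction and no post-operative model can recover
  it; this degenerate configuration is allowed (truth is still defined)
  but not meaningful for recovery experiments.
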