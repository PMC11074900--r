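---
title: "Dietary phenotyping from transaction logs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary phenotyping from transaction logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mealprint` re-implements, as tested code, a digital-phenotyping analysis
that derives dietary-behavior features from campus payment records and
relates them to depression screening outcomes. This vignette is the
package's own account of the science: the models and their assumptions, the
parameters that matter, what the synthetic cohort emulates, and the
decisions taken where the procedure admitted more than one defensible
reading.

## The screening model

Groups are defined solely from self-report totals. PHQ-9 bands give the
depression groups (mild 5–9; moderate–severe ≥ 10). Healthy controls must
additionally be free of comorbid symptoms: GAD-7 < 5, PSS-14 < 29, ISI < 8.
Students below the depression threshold but above any comorbidity threshold
are *excluded* — they are neither cases nor clean controls. The four labels
partition any complete survey table, which the tests assert property-style.

A deliberate wrinkle: the characteristics table flags comorbidity with
strict inequalities (GAD-7 > 5, PSS-14 > 28, ISI > 8) while inclusion uses
≥ 5 / ≥ 29 / ≥ 8. The two rule sets disagree at the boundary (a GAD-7 of
exactly 5 excludes a student from HC but is not flagged). Both are kept
verbatim rather than harmonized; fidelity to the published thresholds beats
tidiness, and the discrepancy is confined to single score values.

## Meal segmentation

Within one student-day, sorted payments are grouped greedily: the first
payment anchors the first meal, and each later payment joins the current
meal iff it falls within 2 hours *of the anchor* (not of the previous
payment). An anchored — rather than sliding — window is the literal reading
of "within 2 hours of this initial record", and it is order-deterministic.
Ties in timestamps are broken by a stable sort on (time, amount, item).

Classification uses the cafeterias' operating slots (breakfast 06:30–08:30,
lunch 11:00–13:00, dinner 17:30–19:30), bounds inclusive at both ends. A
start time outside every slot is assigned to the nearest slot by gap to the
interval, ties toward the earlier slot, and flagged `out_of_slot`; a config
switch (`segment_log(..., out_of_slot = "drop")`) discards such meals
instead, since the source procedure does not say which was done. Days
segmenting into more than three meals keep the three closest to any slot;
duplicate classes within a day keep the in-slot, then earlier, meal. Every
dropped meal lands in an audit attribute, and the tests assert expenditure
conservation across kept plus dropped meals.

## Feature families and statistical indices

All statistics are computed per student, separately for weekdays and
weekends (civil day-of-week; an optional holiday override exists because
October 2020 in China contained a national holiday, but the default is the
pure day-of-week rule — the source is silent).

The dispersion index is the **raw median absolute deviation**,
median(|x − median x|), with *no* 1.4826 consistency factor: reported
values like "17 minutes of lunchtime MAD" are raw deviation magnitudes, not
rescaled SD estimates. A `mad_type = "mean"` toggle covers the possibility
that "MAD" denoted the mean absolute deviation, which the text does not
exclude.

Two frequency denominators required decisions, since the defining formulas
are unreadable in the source:

* **All-day pattern frequencies** divide by days with ≥ 1 recorded meal. A
  day with no record is indistinguishable from off-campus eating, so it is
  treated as unobserved rather than as "ate nothing" (switchable to
  calendar-days).
* **Meal-class frequencies** divide by all calendar days of the day type,
  because skipping itself is the signal of interest — a student recorded on
  11 of 22 weekdays with breakfast each time has breakfast frequency 0.5,
  not 1.

Z-scores for banding and classification are computed over the full included
cohort (all three groups pooled), using the sample (n−1) SD — the
convention of the statistics software family the analysis descends from; a
`sd_type = "population"` toggle exists. Bands are Rare (z < −1), Normal
(|z| ≤ 1), Always (z > 1). Zero-variance features are dropped with a
message, never silently imputed.

## Inference

* **ANCOVA.** `feature ~ group + age + gender + bmi_class + education`,
  group effect by the partial F-test of the group dummies (identical to
  Type II sums of squares in this main-effects design). Post hoc pairwise
  contrasts of adjusted means come directly from the coefficient vector and
  are cross-checked against `emmeans` in the tests; BH-FDR applies across
  the 3 pairs within a feature, and across features within a family for the
  group effect (the FDR family is configurable; "per feature family" is the
  default since the published correction scope is unstated).
* **Logistic associations.** Two binary models (each depression level vs
  HC) rather than one multinomial fit, because per-level odds ratios
  against HC are what the source reports; Rare is the reference band since
  results are shown only for Normal and Always. Wald CIs
  (exp(B ± 1.96 SE)); suspected separation flags the estimate unstable
  rather than swapping in a penalized fit.
* **Mediation.** Single-mediator product-of-paths: `M ~ X + cov` (path a),
  `Y ~ X + M + cov` (path b, direct c′), indirect = a·b with a percentile
  bootstrap CI (default 5000 resamples, seed mandatory). The published
  description contradicts itself on variable roles — it names the pattern
  the independent variable yet reports "the indirect effect of groups … on
  breakfast-lunch-dinner pattern". The default follows the reported result
  (X = group 0/1/2, M = raw anxiety total, Y = BLD frequency); a `reverse`
  argument runs the other orientation. The mediator enters as the raw
  GAD-7 total, not a binary flag.

## Detection

An RBF-kernel SVM with C = 0.1 and gamma = 0.001 (the published grid-search
optimum; `grid_search()` reproduces the selection machinery with
independently seeded folds and smaller-C-then-smaller-gamma tie-breaking)
under stratified 5-fold cross-validation. Multiclass precision/recall/F1
are macro-averaged (a weighted option exists); AUC is one-vs-rest from
decision-function scores, avoiding an unstated probability-calibration
step. No class reweighting by default. A consequence worth knowing: at the
realistic 2222/916/172 imbalance these hyperparameters yield an SVM that
largely predicts the majority class, so its accuracy approximates the HC
share — visible in `analysis/06_classify.R` — whereas on balanced synthetic
groups the same harness genuinely separates the classes. The binary
(HC vs moderate–severe) task is easier than the 3-class task in both
regimes.

## The synthetic cohort: what it does and does not emulate

The generator encodes, per group, the qualitative contrasts the analysis is
meant to detect, with defaults chosen once as the packaged study
conditions:

* **Timing.** Meal times are normal, truncated to the operating slot.
  Jitter SDs (seconds) — breakfast 900/930/1000, lunch 1520/1565/1690,
  dinner 2080/2105/2330 for HC/mild/moderate-severe — were calibrated from
  the reported dispersion magnitudes via MAD ≈ 0.6745 σ (lunch MADs of
  roughly 17.1/17.6/19.0 min, dinner 23.4/23.7/26.2 min), so the simulated
  cohort reproduces eating-time irregularity of the right order.
* **Skipping.** Weekday breakfast skip probabilities 0.25/0.30/0.45 (higher
  on weekends), lunch and dinner rarely skipped. Breakfast skipping is what
  mechanically produces the lower BLD and higher LD pattern frequencies in
  depression.
* **Spending.** Log-normal per-meal expenditure; dinner log-mean rises from
  2.30 (HC) to 2.42/2.44, making both depression groups spend more at
  dinner, with mild ≈ moderate–severe.
* **Diversity.** Distinct items per meal are 1 + Poisson(rate − 1), rates
  3.0/2.9/2.5, drawn from a 50-item per-cafeteria catalogue. One payment
  may cover several items, so the log's `item_id` column is a "+"-joined
  receipt string.
* **Surveys.** Discretized truncated normals per instrument with locations
  and scales equal to the published group means (SDs); GAD-7 couples to the
  standardized PHQ-9 draw with ρ = 0.5 and clips to its band, so the
  anxiety–depression correlation needed by the mediation machinery exists.
* **Transactions.** 1–3 payments per meal (0.7/0.2/0.1), amounts split by a
  uniform Dirichlet, later payments inside the same slot. Cafeteria
  preferences are identical across groups, matching the null location
  finding.

What it does **not** emulate: any causal pathway from anxiety to eating
*within* groups (the within-group mediation b-path is null by construction,
so the cohort-level indirect effect is near zero — the mediation machinery
is instead validated on purpose-built synthetic path models); menu
economics; holidays and exam weeks; gradual symptom change over the month
(scores are drawn once); off-campus meals; and the messiness of real
payment systems (refunds, shared cards). Passing tests therefore certify
the *pipeline* — segmentation, features, calibration of the inference — not
the epidemiology of any real cohort. By the same token the synthetic
contrasts are cleaner than real ones, so effect sizes and classifier
accuracies on balanced synthetic groups exceed what real data would give.

## Numerical conventions and degenerate inputs

Times are integer seconds since midnight; amounts are rounded to 2 decimals
with the rounding residual folded into a meal's largest payment so amounts
sum exactly to the drawn expenditure. Empty feature sets are missing, never
zero; empty groups report blank percentages. A constant covariate is
dropped before model fitting (it is inestimable next to an intercept);
a rank-deficient design errors naming the aliased columns. Truncated
normals use inverse-CDF sampling, which is exact and vectorizes; a zero SD
collapses to the (clamped) mean. Every stochastic routine takes an explicit
seed, and a single pipeline seed fans out to per-stage seeds through a
fixed derivation so stages are independently reproducible.

## Problem sizes used by the test suite

The suite validates calibration at sizes chosen to make binomial noise
small relative to the asserted bands: 500 replicates for ANCOVA type-I
error and logistic CI coverage (n = 300 each), 200 replicates for mediation
coverage and null rejection (n = 300, 1000 bootstrap resamples), 100
replicates of full cohort generation at 200 students/group for
ground-truth recovery, and one full-scale run at 2222/916/172 for the
FDR-significance check. Oracle-equivalence checks run 1000 random
student-days against a brute-force re-anchoring scan.

## Known limitations

* The published odds ratios, F-values and SVM metrics derive from a
  non-shared cohort and cannot be numerically reproduced; this package
  reproduces the *procedure* and its qualitative findings on ground-truthed
  synthetic data.
* Item identifiers carry no nutritional meaning; diversity is a count, not
  a diet-quality measure.
* The mediation Y-equation is linear even though a frequency outcome is
  bounded; a logistic Y-equation variant was considered and not defaulted,
  as the reported R² is consistent with the linear form.
* Only one wave of screening is supported; no longitudinal modelling.
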