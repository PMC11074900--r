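# mealprint

Digital dietary phenotyping from cafeteria transaction logs.

When students pay for campus meals electronically, the payment log is a
passive, month-long record of *when*, *where*, *how much* and *how varied*
they eat. `mealprint` turns such a log, together with depression-screening
questionnaires (PHQ-9, GAD-7, PSS-14, ISI), into a reproducible analysis of
how dietary behavior differs across depression severity — and of whether
those behaviors can detect depression at all. Because raw student payment
records cannot be shared, the package ships a synthetic-cohort generator
that emulates the group-conditional structure of such data (breakfast
skipping, meal-time jitter, dinner-expenditure shifts, item diversity,
coupled screening scores) with known ground truth, so every statistical
claim in the pipeline can be tested against parameters that are known by
construction.

It is written for biostatisticians and digital-phenotyping researchers who
want an auditable reference implementation of this class of analysis.

## The method

1. **Screening.** PHQ-9 bands define groups: mild depression 5–9,
   moderate–severe ≥ 10; healthy controls (HC) need PHQ-9 < 5 *and*
   GAD-7 < 5, PSS-14 < 29, ISI < 8. Students with PHQ-9 < 5 but comorbid
   symptoms above threshold are screened out.
2. **Meal segmentation.** Within a student-day, payments within 2 h of a
   meal's first payment form one meal (greedy anchored window); meal time is
   the anchor timestamp, expenditure the sum of member amounts. Start times
   map to the cafeteria operating slots — breakfast 06:30–08:30, lunch
   11:00–13:00, dinner 17:30–19:30 — with out-of-slot meals reassigned to
   the nearest slot and flagged.
3. **Features.** Six families per student, split by weekday/weekend: meal
   timing statistics (mean, median, raw MAD = median |x − median x|, max,
   min), inter-meal intervals, expenditure, cafeteria visit shares, daily
   item diversity, meal frequencies, and frequencies of the 7 all-day
   patterns (B, L, D, BL, LD, BD, BLD — the set of meals eaten in a day).
4. **Inference.** ANCOVA per feature (covariates: age, gender, BMI class,
   education) with a partial F-test for the group effect and BH-FDR
   corrected post hoc contrasts; logistic regression of depression status on
   SD-banded pattern frequencies (Rare z < −1 / Normal / Always z > 1,
   reference Rare) giving odds ratios with Wald CIs; and single-mediator
   analysis (group → anxiety → breakfast–lunch–dinner pattern) with a
   5000-resample percentile bootstrap CI for the indirect effect a·b.
5. **Detection.** RBF-kernel SVM (C = 0.1, gamma = 0.001) on z-scored
   features under stratified 5-fold cross-validation, for the 3-class and
   the binary (HC vs moderate–severe) tasks, reporting accuracy, macro
   precision/recall/F1 and one-vs-rest AUC from decision scores.

## Worked example

```r
library(mealprint)

cfg <- sim_config(n_per_group = c(HC = 200, mild = 200, moderate_severe = 200),
                  seed = 7)
cohort <- generate_cohort(cfg)
meals  <- segment_log(cohort$transactions)
feats  <- extract_features(meals, cfg$calendar)
labels <- assign_group(cohort$survey)

idx <- match(feats$student_id, cohort$survey$student_id)
ancova(feats[["time.weekday.lunch.mad"]], labels[idx],
       covariate_set(cohort$survey[idx, ]))
```

```
ANCOVA group effect: F(2, 592) = 5.552, p = 0.004083 (n = 600)
               contrast estimate       se           t          p       p_adj
              mild - HC -2.13879 27.16257 -0.07874032 0.93726578 0.937265780
   moderate_severe - HC 77.46849 27.21451  2.84658781 0.00457222 0.006858329
 moderate_severe - mild 79.60728 27.20028  2.92670835 0.00355718 0.006858329
```

The moderate–severe group's weekday lunchtime MAD is about 77 s larger than
HC after covariate adjustment, and the contrast survives FDR correction —
the group eats lunch at noticeably less regular times, exactly the
irregularity the generator encodes. The mild–HC contrast is small and
non-significant, matching its nearly identical timing-jitter preset.

The full study-scale analysis is organised as numbered drivers:

```sh
Rscript analysis/01_simulate.R   # 3310 students, October 2020, ~360k payments
Rscript analysis/02_screen.R
Rscript analysis/03_segment.R
Rscript analysis/04_features.R
Rscript analysis/05_stats.R
Rscript analysis/06_classify.R
```

Each stage writes its tables under `results/` and prints what it found.

## Vignette

`vignettes/dietary-phenotyping.Rmd` documents the model assumptions, every
tunable parameter with its default and rationale, what the synthetic cohort
does and does not emulate, and the package's numerical conventions.
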