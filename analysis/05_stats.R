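#!/usr/bin/env Rscript
# Stage 5: group comparisons, pattern associations, mediation.
#
# ANCOVA (age, gender, BMI class, education as covariates) across every
# feature with family-wise FDR on the group effect and BH-corrected post hoc
# contrasts; SD-band (Rare/Normal/Always) logistic models of the weekday
# BLD and LD pattern frequencies against each depression level vs HC; and
# the single-mediator bootstrap model group -> anxiety -> BLD frequency.

suppressMessages(library(mealprint))
suppressMessages(library(data.table))

features <- fread("results/features.csv")
survey <- read_survey("results/data/survey.csv")
labels_df <- fread("results/group_labels.csv")
labels <- labels_df$group[match(survey$student_id, labels_df$student_id)]

anc <- run_group_comparisons(features, survey, labels)
fwrite(anc, "results/stats_ancova.csv")
sig <- unique(anc$feature[anc$p_group_fdr < 0.05])
cat("features with FDR-significant group effects:", length(sig), "of",
    length(unique(anc$feature)), "\n")
key <- c("time.weekday.lunch.mad", "time.weekday.dinner.mad",
         "freq.weekday.breakfast", "expenditure.weekday.dinner.mean",
         "pattern.weekday.BLD", "pattern.weekday.LD")
print(unique(anc[anc$feature %in% key, c("feature", "F", "p_group", "p_group_fdr")]))

logi <- run_pattern_associations(features, survey, labels)
fwrite(logi, "results/stats_logistic.csv")
cat("\npattern-band odds ratios (reference band: Rare):\n")
print(logi[, c("pattern", "outcome", "band", "or", "ci_lo", "ci_hi", "p")])

med <- run_mediation(features, survey, labels, n_boot = 5000L,
                     seed = 20201005L)
print(med)
jsonlite::write_json(med[c("a", "b", "c_prime", "indirect", "ci",
                           "r_squared", "n", "n_boot")],
                     "results/stats_mediation.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/stats_ancova.csv, stats_logistic.csv, stats_mediation.json\n")
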