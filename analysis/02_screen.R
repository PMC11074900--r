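#!/usr/bin/env Rscript
# Stage 2: screen the cohort into severity groups.
#
# Applies the PHQ-9 screening bands (mild 5-9, moderate-severe >= 10) and
# the healthy-control comorbidity cutoffs (GAD-7 < 5, PSS-14 < 29, ISI < 8);
# students without depressive symptoms but with comorbid symptoms above
# threshold are screened out. Writes the group labels and a Table-1 style
# characteristics summary.

suppressMessages(library(mealprint))

survey <- read_survey("results/data/survey.csv")
labels <- assign_group(survey)
excl <- exclusion_count(nrow(survey), labels)

cat("recruited:", nrow(survey), "\n")
print(table(labels))
cat("screened out:", excl$n_excluded, "; included:", excl$n_included, "\n")

write.csv(data.frame(student_id = survey$student_id, group = labels),
          "results/group_labels.csv", row.names = FALSE)
summ <- cohort_summary(survey, labels)
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)
writeLines(format_cohort_summary(summ), "results/cohort_summary.txt")
cat("wrote results/group_labels.csv, results/cohort_summary.{csv,txt}\n")
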