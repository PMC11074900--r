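#!/usr/bin/env Rscript
# Stage 4: extract the six dietary feature families.
#
# Per student and day type (weekday/weekend): meal-time statistics (mean,
# median, MAD, max, min), inter-meal intervals, expenditure statistics,
# cafeteria visit shares, daily item diversity, meal frequencies, and the
# frequencies of the 7 all-day patterns. Only included (screened-in)
# students with at least one meal enter the feature table.

suppressMessages(library(mealprint))
suppressMessages(library(data.table))

meals <- fread("results/meals.csv")
meals[, start_time := hms_to_seconds(start_time)]
labels <- fread("results/group_labels.csv")
cal <- study_calendar(min(meals$date), max(meals$date))

features <- extract_features(meals, cal)
included <- labels$group[match(features$student_id, labels$student_id)] %in%
  c("HC", "mild", "moderate_severe")
cat("students with >= 1 meal:", nrow(features),
    "; entering analysis:", sum(included), "\n")
features <- features[included]

fwrite(features, "results/features.csv")
fwrite(feature_dictionary(features), "results/feature_dictionary.csv")
cat("wrote results/features.csv (", ncol(features) - 1, "features ),",
    "results/feature_dictionary.csv\n")
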