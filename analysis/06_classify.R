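#!/usr/bin/env Rscript
# Stage 6: depression detection from dietary features.
#
# RBF-kernel SVM (C = 0.1, gamma = 0.001) on the z-scored feature table
# under stratified 5-fold cross-validation, for the 3-class task
# (HC / mild / moderate-severe) and the binary task (HC vs moderate-severe).

suppressMessages(library(mealprint))
suppressMessages(library(data.table))

features <- fread("results/features.csv")
labels_df <- fread("results/group_labels.csv")
grp <- labels_df$group[match(features$student_id, labels_df$student_id)]

z <- suppressMessages(zscore_and_band(as.matrix(features[, !"student_id"]))$z)
ok <- colSums(is.na(z)) == 0
cat("features entering the classifier:", sum(ok), "of", ncol(z),
    "(complete columns)\n")

cfg <- svm_config(seed = 20201006L)  # C = 0.1, gamma = 0.001, 5 folds
tri <- crossval_svm(z[, ok, drop = FALSE], grp, cfg)
print(tri)
bsel <- grp %in% c("HC", "moderate_severe")
bin <- crossval_svm(z[bsel, ok, drop = FALSE], grp[bsel], cfg)
print(bin)

mdf <- rbind(data.frame(task = "HC vs mild vs moderate-severe",
                        t(tri$summary)),
             data.frame(task = "HC vs moderate-severe", t(bin$summary)))
fwrite(mdf, "results/metrics.csv")
jsonlite::write_json(list(triclass = as.list(tri$summary),
                          binary = as.list(bin$summary)),
                     "results/metrics.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/metrics.{csv,json}\n")
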