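#!/usr/bin/env Rscript
# Stage 3: segment payments into meals.
#
# Groups each student-day's payments with the anchored 2-hour rule,
# classifies meal starts into the breakfast/lunch/dinner operating slots,
# keeps at most one meal per class per day and logs everything dropped.

suppressMessages(library(mealprint))

tx <- read_transactions("results/data/transactions.csv")
meals <- segment_log(tx)
dropped <- attr(meals, "dropped")

cat("transactions:", nrow(tx), "-> meals:", nrow(meals),
    "(", nrow(dropped), "dropped )\n")
print(table(meals$meal_class))
cat("out-of-slot (reassigned, flagged):", sum(meals$out_of_slot), "\n")

write_meals_csv(meals, "results/meals.csv")
if (nrow(dropped)) write.csv(dropped, "results/meals_dropped.csv",
                             row.names = FALSE)
cat("wrote results/meals.csv\n")
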