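#!/usr/bin/env Rscript
# Step 4 — interaction indices and coculture outcome classification.
#
# Each coculture x parameter gets the monoculture-referenced interaction
# index and an outcome class: A (no perceived interaction), B
# (overyielding), C (underyielding), D (intermediate but off-average),
# from the Welch t-test decision ladder.

library(cocult)

params <- readr::read_csv("results/growth_parameters.csv",
                          show_col_types = FALSE)
records <- analyze_interactions(params, alpha = 0.05)
summary_tbl <- outcome_summary(records)

readr::write_csv(records, "results/interactions.csv")
readr::write_csv(summary_tbl, "results/outcome_summary.csv")

cat("Outcome classes per parameter (counts over",
    summary_tbl$n_total[1], "cocultures):\n")
print(as.data.frame(summary_tbl), digits = 3)
cat("\nStrongest positive and negative AUC interactions:\n")
auc <- records[records$parameter == "auc", ]
auc <- auc[order(auc$index), ]
print(as.data.frame(rbind(head(auc, 3), tail(auc, 3))[,
  c("strain_1", "strain_2", "index", "outcome", "direction")]), digits = 2)
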