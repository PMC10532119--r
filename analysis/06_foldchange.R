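#!/usr/bin/env Rscript
# Step 6 — relative-abundance fold changes from cytometry.
#
# Gate counts become relative abundances; each strain-in-pair's fold
# change (T24 share / T0 share) is tested against 1 across the four
# replicates.

library(cocult)

cyto <- read_cytometry("results/data/cytometry.csv")
layout <- read_layout("results/data/layout.csv")
ft <- fold_change_table(cyto, layout, alpha = 0.05)

readr::write_csv(ft$summary, "results/fold_changes.csv")

s <- ft$summary[ft$summary$kind == "coculture", ]
cat(nrow(s), "strain-in-pair fold changes;",
    sum(s$significant, na.rm = TRUE), "significantly different from 1\n\n")
s <- s[order(s$mean_fc), ]
cat("Largest composition losses (fold change << 1):\n")
print(as.data.frame(head(s[, c("focal", "partner", "mean_fc", "sd_fc",
                               "p_value")], 5)), digits = 2)
cat("\nLargest composition gains:\n")
print(as.data.frame(tail(s[, c("focal", "partner", "mean_fc", "sd_fc",
                               "p_value")], 5)), digits = 2)
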