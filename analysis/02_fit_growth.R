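#!/usr/bin/env Rscript
# Step 2 — logistic growth fitting and kinetic-parameter extraction.
#
# Every well's OD600 curve is truncated to 24 h and fitted with the
# logistic model; latency (OD > 0.25) and maxOD are measured directly,
# r and the model-based AUC come from the fit.

library(cocult)
library(dplyr)

curves <- read_timeseries("results/data/timeseries.csv")
layout <- read_layout("results/data/layout.csv")
joined <- join_layout_curves(curves, layout)

params <- inner_join(layout, fit_growth(curves), by = "well")
readr::write_csv(params, "results/growth_parameters.csv")

cat("Fitted", nrow(params), "wells;", sum(params$converged),
    "fits converged\n\n")
mono <- params |>
  filter(kind == "monoculture") |>
  group_by(species_a) |>
  summarise(across(c(auc_odh, r_per_h, max_od, latency_h),
                   \(x) mean(x, na.rm = TRUE)), .groups = "drop")
cat("Monoculture species means:\n")
print(as.data.frame(mono), digits = 3)
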