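#!/usr/bin/env Rscript
# Step 3 — species and strain effects in monocultures.
#
# Nested ANOVA per kinetic parameter: the species effect is tested against
# the strain-within-species mean square, the strain effect against the
# residual; Tukey-style compact letter displays summarise which species
# differ.

library(cocult)

params <- readr::read_csv("results/growth_parameters.csv",
                          show_col_types = FALSE)
stats <- monoculture_stats(params, alpha = 0.05)

readr::write_csv(stats$tests, "results/monoculture_stats.csv")
readr::write_csv(stats$groups, "results/species_groups.csv")

cat("Nested ANOVA per parameter:\n")
print(as.data.frame(stats$tests), digits = 3)
cat("\nSpecies letter groups (AUC):\n")
print(as.data.frame(stats$groups[stats$groups$parameter == "auc", ]),
      digits = 3)
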