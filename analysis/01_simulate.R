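#!/usr/bin/env Rscript
# Step 1 — generate the in-silico study design.
#
# Emits the full design: 15 strains (5 species x 3), 15 monocultures in
# triplicate and 105 pairwise cocultures in quadruplicate, OD600 every
# 30 min for 24 h, and 10 000-event cytometry per coculture at T0/T24.
# The species-block scenario plants antagonism among the three strong
# fermenters (Sc, Lt, Td) and facilitation in all S. bacillaris pairs,
# with strain-level jitter — the structure the downstream steps should
# recover.

library(cocult)

out <- "results/data"
scen <- scenario_species_block(seed = 42)
paths <- emit_dataset(scen, out)

ds <- attr(paths, "dataset")
cat("Wrote", length(paths), "files to", out, "\n")
cat("  wells:       ", nrow(ds$layout), "\n")
cat("  monocultures:", sum(ds$layout$kind == "monoculture"), "\n")
cat("  cocultures:  ", sum(ds$layout$kind == "coculture"), "\n")
cat("  cytometry samples:",
    nrow(unique(ds$cytometry[, c("culture_id", "timepoint")])), "\n")
signs <- table(ds$truth$pairs$auc_sign_true)
cat("Planted AUC interaction signs:",
    paste(names(signs), signs, collapse = ", "), "\n")
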