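#!/usr/bin/env Rscript
# Step 7 — single-command end-to-end reproduction.
#
# run_all() re-executes the whole pipeline (simulation included) under one
# config and writes every stage output plus a plain-text report; rerunning
# with the same seed is hash-identical.

library(cocult)

cfg <- pipeline_config(seed = 42, output_dir = "results/run_all")
bundle <- run_all(cfg)
cat("\n", paste(report(bundle), collapse = "\n"), "\n", sep = "")
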