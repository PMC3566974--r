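#!/usr/bin/env Rscript
# Step 4: dumbbell figure.
#
# Re-runs the validation grid on the step-1 datasets and draws, per
# prevalence stratum (LP / IP / HP), the pre-test probability and the
# post-positive / post-negative probabilities for every evaluated
# dataset x rule cell.

suppressMessages(library(cprvalid))

datasets <- lapply(preset_names(), function(nm)
  read_dataset(file.path("results/data", paste0(nm, "_synth.csv")), name = nm))
names(datasets) <- preset_names()

report <- run_validation(datasets)
render_dumbbell(report, "results/dumbbell.pdf", width = 9, height = 7)
cat("Wrote results/dumbbell.pdf\n")
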