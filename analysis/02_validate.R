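#!/usr/bin/env Rscript
# Step 2: run the full multi-dataset external validation.
#
# Reads the synthetic datasets from step 1, applies the six rules/guidelines
# under the complete-case policy with dataset-eligibility checks and the
# derivation exclusion, and writes the accuracy grid (one row per dataset x
# rule x cutoff) plus the full JSON report.

suppressMessages(library(cprvalid))

meta <- list(vandenbruel = c("mixed", "BE"), roukema = c("ED", "NL"),
             bleeker = c("ED", "NL"), monteny = c("GP", "NL"),
             brent = c("ED", "UK"), thompson = c("PAU", "UK"),
             oostenbrink = c("ED", "NL"))
datasets <- lapply(names(meta), function(nm)
  read_dataset(file.path("results/data", paste0(nm, "_synth.csv")),
               name = nm, setting = meta[[nm]][1], country = meta[[nm]][2]))
names(datasets) <- names(meta)

report <- run_validation(datasets)
print(report)

tab <- report_to_table(report)
ev <- tab[tab$status == "evaluated", ]
cat("\nDatasets validating each rule:\n")
print(table(unique(ev[c("dataset", "rule_id")])$rule_id))

cat("\nRule-out adequate (sens > 90%, NLR <= 0.2) cells:\n")
print(as.data.frame(ev[which(ev$rule_out),
                       c("dataset", "rule_id", "cutoff", "stratum", "sens", "lr_neg")]))

write_report_tsv(report, "results/validation_grid.tsv")
write_report_json(report, "results/validation_report.json")
cat("\nWrote results/validation_grid.tsv and results/validation_report.json\n")
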