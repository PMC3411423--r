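#!/usr/bin/env Rscript
# Generate the synthetic study cohort (patients, providers, healthy
# controls) and the patient retest wave under the calibrated defaults, and
# write them out as CSV for the downstream steps.
#
# Usage: Rscript analysis/01_simulate.R [seed]
library(bcsdqi)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20120608L
dir.create("results", showWarnings = FALSE)

cfg <- default_generator_config()
cohort <- generate_cohort(cfg, seed = seed)
retest <- generate_retest(cohort, cfg, seed = seed + 1L)

write_cohort(cohort, "results/cohort.csv")
write_cohort(retest, "results/retest.csv")
write_item_bank(cohort$item_bank, "results/item_bank.yaml")
write_goal_bank(cohort$goals, "results/goal_bank.yaml")

print(cohort)
v <- validate_cohort(cohort)
print(v)
s <- summarize_cohort(cohort)
print(s)

cat("\nWrote results/cohort.csv (", nrow(cohort$records), " records) and ",
    "results/retest.csv (", nrow(retest$records), " records), seed ", seed,
    "\n", sep = "")
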