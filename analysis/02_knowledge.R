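#!/usr/bin/env Rscript
# Knowledge scoring and item-retention diagnostics: score the cohort with
# the initial, reduced and screener item sets, summarize the group
# distributions, and run the retention heuristics.
#
# Usage: Rscript analysis/02_knowledge.R   (expects results/ from step 01)
library(bcsdqi)

cohort <- read_cohort("results/cohort.csv",
                      read_item_bank("results/item_bank.yaml"),
                      read_goal_bank("results/goal_bank.yaml"))

for (set in c("initial", "reduced", "screener")) {
  ss <- score_cohort(cohort, set)
  cat("\n---- ", set, " item set ----\n", sep = "")
  print(ss)
  utils::write.csv(ss$summary,
                   sprintf("results/knowledge_%s_summary.csv", set),
                   row.names = FALSE)
}

diag <- item_diagnostics(cohort)
cat("\n---- item diagnostics (initial set) ----\n")
print(diag)
utils::write.csv(diag$items, "results/item_diagnostics.csv", row.names = FALSE)

pat <- cohort$records[cohort$records$group == "patient" &
                        cohort$records$wave == "test", ]
r_sf <- cor(bcsdqi:::score_records(pat, cohort$item_bank, "screener"),
            bcsdqi:::score_records(pat, cohort$item_bank, "reduced"),
            use = "complete.obs")
cat(sprintf("\nScreener vs full knowledge score, Pearson r = %.2f\n", r_sf))

ss <- score_cohort(cohort, "reduced")
d <- discriminant_validity(ss, cohort)
cat(sprintf("Provider-patient contrast: %.1f points, p = %.2g\n",
            d$contrasts$diff[1], d$contrasts$p[1]))
cat(sprintf("Patient-control contrast: %.1f points, p = %.2g\n",
            d$contrasts$diff[2], d$contrasts$p[2]))
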