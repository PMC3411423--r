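#!/usr/bin/env Rscript
# Psychometric evaluation: retest reliability, content / discriminant /
# predictive validity, preference gradient and feasibility, bundled with
# the audit manifest.
#
# Usage: Rscript analysis/04_psychometrics.R   (expects results/ from 01)
library(bcsdqi)

bank <- read_item_bank("results/item_bank.yaml")
goals <- read_goal_bank("results/goal_bank.yaml")
cohort <- read_cohort("results/cohort.csv", bank, goals)
retest <- read_cohort("results/retest.csv", bank, goals)

audit <- run_audit(cohort = cohort, retest = retest)
psy <- audit$psychometrics

cat("---- retest reliability (a priori target ICC > 0.7) ----\n")
rel <- psy$reliability
rel$icc <- round(rel$icc, 2)
print(rel, row.names = FALSE)

cat("\n---- content validity ----\n")
cat(sprintf("Providers rating coverage very/extremely well: %.1f%% (target > 70%%)\n",
            psy$content$provider_coverage$pct_very_or_extremely))
gt <- psy$content$goal_top3
gt[, c("overall_pct", "mastectomy_pct", "lumpectomy_pct")] <-
  round(gt[, c("overall_pct", "mastectomy_pct", "lumpectomy_pct")], 1)
print(gt, row.names = FALSE)

cat("\n---- discriminant validity ----\n")
cat(sprintf("Group ANOVA p = %.2g\n", psy$discriminant$anova_p))
print(within(psy$discriminant$contrasts,
             { diff <- round(diff, 1); t <- round(t, 2) }), row.names = FALSE)
print(within(psy$discriminant$goal_tests, {
  mean_mastectomy <- round(mean_mastectomy, 1)
  mean_lumpectomy <- round(mean_lumpectomy, 1)
  diff_expected_direction <- round(diff_expected_direction, 2)
}), row.names = FALSE)

cat("\n---- preference gradient ----\n")
print(round(psy$preference$means, 2))
cat(sprintf("ANOVA p = %.2g\n", psy$preference$anova_p))

cat("\n---- predictive validity ----\n")
cat(sprintf("Confidence %.2f (concordant) vs %.2f (discordant), p = %.2f\n",
            psy$predictive$confidence$means[["concordant"]],
            psy$predictive$confidence$means[["discordant"]],
            psy$predictive$confidence$p))
cat(sprintf("Would choose the same again: %.0f%% vs %.0f%%, p = %.2f\n",
            psy$predictive$regret$pct_same_again[["concordant"]],
            psy$predictive$regret$pct_same_again[["discordant"]],
            psy$predictive$regret$p))

cat("\n---- feasibility ----\n")
fz <- psy$feasibility
cat(sprintf("Knowledge items: %.1f%% missing on average; goals: median %.1f%%\n",
            fz$knowledge_missing_mean, fz$goal_missing_median))
cat("Items above the 5% threshold:",
    if (length(fz$offenders)) paste(fz$offenders, collapse = ", ") else "none",
    "\n")
cat(sprintf("Completion time %.1f min (range %.1f-%.1f); by education %s, ANOVA p = %.2g\n",
            fz$completion$mean, fz$completion$range[1], fz$completion$range[2],
            paste(round(fz$completion$by_education, 1), collapse = "/"),
            fz$completion$anova_p))

write_audit(audit, "results/audit")
cat("\nFull bundle written to results/audit/\n")
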