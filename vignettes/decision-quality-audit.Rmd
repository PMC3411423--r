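---
title: "Auditing decision quality in breast cancer surgery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing decision quality in breast cancer surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcsdqi)
```

## The measurement problem

For early-stage invasive breast cancer, mastectomy and lumpectomy with
radiation are survival-equivalent, so the "right" operation depends on how
each patient weighs keeping her breast, avoiding radiation, peace of mind,
and related concerns. A decision-quality instrument for this choice asks
two questions: were patients *informed* (a knowledge score), and did they
receive treatments that *match their goals* (a concordance score)? This
package implements the scoring rules, the concordance model and the full
psychometric evaluation of such an instrument, together with a calibrated
synthetic-cohort generator, so the whole audit can be developed, tested and
demonstrated end to end. Registry-identified survey data of this kind are
not publicly deposited; the synthetic cohort is therefore a first-class,
tested component, not a stand-in fixture.

## Knowledge scoring

Each of the 15 instrument items (13 multiple choice, 2 open ended) is worth
one point. The rules, in order of application:

* a correct response scores 1; open-ended answers are correct when they
  fall inside a clinically pre-determined interval `[lo, hi]`;
* "I am not sure" is an *answered, incorrect* response and scores 0 — it is
  never conflated with a skipped item;
* a skipped item scores `1/k`, where `k` counts the response choices
  including "I am not sure" — the expected score of blind guessing, so
  skipping is neither rewarded nor punished relative to guessing;
* items with multiple parts weight their parts to sum to one;
* a respondent's score is `100 * points / |item set|`, and is defined only
  when at least half of the set's items were answered (answered includes
  "not sure"; the rule counts items, not parts).

For open-ended items `k` has no printed value; the default bank uses
`k = 10`, reflecting that a blind guess rarely lands inside the accepted
range. Real instruments supply their own `k` per item in the bank
configuration.

Three item sets are scored: the 15-item initial set, the 12-item reduced
set used for all headline results (three items were dropped during item
review), and a 5-item screener. Item-retention diagnostics follow the
published heuristics exactly: too easy when healthy controls exceed 80%
correct, too hard when providers average under 50%, redundant when an
inter-item correlation exceeds 0.8, problematic when over 5% of responses
are missing, plus a negative corrected item-total correlation
(item against the total *excluding* that item — the corrected form is the
standard choice and is our interpretation, as the source analysis does not
specify it). The flags are advisory: final set membership is a bank
configuration, because retention was a review-panel judgement that the
statistics informed rather than dictated.

## The concordance model

Patients whose disease forced their treatment (lumpectomy followed by
mastectomy, typically for positive margins) are excluded, as are patients
with no definitive surgery recorded. Missing goal ratings are imputed
under a joint multivariate-normal model fitted by
expectation-maximization: the E-step fills each missing block with its
conditional expectation given the observed block and accumulates the
conditional covariance into the second moments; the M-step re-estimates
the mean and covariance. The observed-data log-likelihood is asserted
non-decreasing at every iteration; convergence is the largest absolute
parameter change falling below 1e-6 (cap 500 iterations, error on
failure). Imputed values are clipped to the 0-10 rating scale but *not*
rounded, preserving the conditional means; observed entries are never
altered.

Treatment (mastectomy vs lumpectomy) is then regressed on the stage II
indicator and all six goal ratings by maximum-likelihood logistic
regression (IRLS, tolerance 1e-8, cap 100 iterations; Wald 95% intervals;
a coefficient above 15 in absolute value raises a separation warning). All
six goals enter the model even though only three reach significance — the
analysis plan examined stage and each goal, and blank rows in a published
table mean non-significant, not excluded. A patient is concordant when the
predicted probability of mastectomy is at least 0.5 and mastectomy was
received, or below 0.5 and lumpectomy was received; the 0.5 boundary
counts as predicted mastectomy, exactly as specified. The concordance
score is the percentage concordant. There is deliberately no train/test
split: the score is an in-sample goodness-of-fit summary describing how
well treatments track goals in the audited group. Model discrimination is
summarized by the rank-based c-statistic (ties count one half).

## Psychometric battery

* **Reliability.** Test-retest agreement is the intraclass correlation in
  the two-way random-effects, absolute-agreement, single-measurement form,
  computed from the ANOVA mean squares
  `(MSR - MSE) / (MSR + MSE + 2 (MSC - MSE) / n)`. The source analysis says
  only "ICC"; this form is the standard test-retest choice and is recorded
  here as an interpretation. Incomplete pairs are dropped listwise per
  measure. The a priori target is 0.7.
* **Content validity.** Providers rate how well the items cover the key
  facts (1-4); the pass mark is more than 70% rating 3-4. Each goal passes
  when at least 20% of patients place it in their top three.
* **Discriminant validity.** One-way ANOVA of knowledge over
  provider/patient/control with planned one-sided comparisons (providers
  above patients, patients above controls) using the pooled error term;
  per-goal one-sided Welch t-tests by surgery received, in the direction
  declared by the goal bank; and an ordered preference gradient
  (mastectomy-preferring patients should carry higher model probabilities
  than unsure patients, who should exceed lumpectomy-preferring ones).
  Welch (unequal-variance) t-tests are used throughout where the analysis
  plan says only "t-tests". Planned contrasts use a per-contrast alpha of
  0.05 with no multiplicity adjustment, since none was pre-specified; the
  report flags this.
* **Predictive validity.** Confidence (two-sided Welch t) and regret
  (dichotomized as definitely/probably yes against the rest, chi-square
  without continuity correction) compared between concordant and
  discordant patients. These tests run on the analyzable subset, since the
  concordance flag only exists there.
* **Feasibility.** Per-item missingness with a 5% problem threshold, and
  completion time by education level (one-way ANOVA).

Cronbach's alpha is intentionally absent: the knowledge items do not draw
from a single construct, so internal consistency is not a meaningful
summary for this instrument.

## What the synthetic cohort emulates

`generate_cohort()` draws three groups (440 patients, 88 providers, 35
healthy controls by default) and `generate_retest()` re-administers the
instrument to a 100-patient subsample (the published design retested "a
subset" of unstated size; 100 is our default and is configurable).

**Knowledge.** Responses follow a latent-trait threshold model. Each
respondent carries a standard-normal trait, each respondent-part pair a
stable knowledge residual, and each wave an independent disturbance; the
three loadings square-sum to one, so per-part correct probabilities are
set directly per group. The five published items use their printed
response counts (e.g. 245/433 patients correct on survival equivalence);
the ten unpublished items are synthetic, with profiles calibrated through
per-group probit shifts so that the reduced-set group means land on
52.7/87.7/49.3 with a patient SD of 21.8. The trait loading (0.46 after
calibration) sets the score spread; the stable loading sets test-retest
reliability (target ICC 0.70). Two deliberately easy items and one
reverse-keyed item reproduce the three deletions the item review made, so
the diagnostics have something real to find. Incorrect responses split
between "I am not sure" and the wrong options; item-level missingness is
1.4% throughout.

**Goals and treatment.** The six modelled goals are a latent multivariate
normal plus per-wave measurement noise, rounded and clipped to the 0-10
grid; the recurrence concern's ceiling (88% rating 10) comes from a latent
mean above 10, not a point mass. Correlations follow a single-factor
structure — a mastectomy-leaning attitude loading positively on
remove-breast, avoid-radiation and hassle, negatively on keep-breast —
which is positive semi-definite by construction and gives the observed
keep-remove correlation of -0.46. Goals are generated *first*; treatment
is then drawn Bernoulli(logistic(b0 + b'x)) from the observed, discretized
ratings and stage, with b fixed at the logs of the published odds ratios
(0.79, 1.88, 1.23 per rating point; 1.81 for stage II). Because the
analysis refits exactly this family, simulate-and-refit is a fair
parameter-recovery experiment rather than a tautology. The intercept is
calibrated so that 111/383 of analyzable patients have mastectomy. Of 440
patients, 28 report no definitive surgery and 29 (7% of the remainder) had
lumpectomy followed by mastectomy; both groups are generated and then
excluded downstream, mirroring the published analysis set. The published
count tables are not fully reconcilable (440 patients with 168 mastectomies
overall versus 111/272 in the model table); the generator targets the
analysis-set figures and leaves the totals configurable.

**Everything else.** Preference is a noisy monotone cut of the true
treatment probability, calibrated so the model-probability means by stated
preference approximate the published 0.70/0.30/0.08 gradient (a
one-dimensional monotone cut reaches about 0.72/0.34/0.04 because the
predicted probabilities pile near zero; the ordering and its significance
reproduce exactly); confidence is high and *independent* of
concordance (the study found no confidence/regret difference, attributed
to a ceiling effect, and the generator reproduces that null); regret,
education, completion times (lognormal, means 6.8/6.4/5.3 minutes by
education), demographics and provider coverage ratings (76% rating 3-4)
follow the published marginals. The remove-breast goal's 10.9%
missingness is placed 94% among lumpectomy patients — missingness that
depends on treatment, hence *not* missing at random given goals alone,
which is exactly the stress the EM step faces in the real data.

**Calibration.** Free parameters (unpublished item profiles, loadings,
latent goal means/SDs/factor loadings, wave noise, intercept) were tuned
with `calibrate_generator()` — damped secant coordinate updates on
Monte-Carlo estimates — against the published summaries: group knowledge
means, the treatment-arm goal means, the keep-remove correlation, the
analyzable mastectomy fraction, and the retest ICCs (0.87/0.83/0.66/0.76/
0.64/0.61 for the goals, 0.70 for knowledge). The resulting constants are
frozen as `default_generator_config()`; the c-statistic (0.95) and the
concordance score (89%) are *emergent* under those conditions, which is
itself evidence that the published numbers are internally consistent.

**What the generator does not emulate.** Recruitment and non-response,
site effects, item wordings for the ten unpublished items, within-person
drift over the retest interval beyond exchangeable wave noise, section-level
skipping (the rare respondent who leaves enough items blank to fall under
the 50% completion floor — missingness here is independent per item), and
any real-data deviation from the latent-normal goal shapes. Passing tests on
this cohort show the pipeline's statistics are implemented and wired
correctly under realistic structure; they cannot certify behaviour on
survey quirks the generative model lacks.

## Numerical choices and degenerate inputs

* Missing cells are empty or `NA` in files; `"not_sure"` is a distinct
  token. Unparseable or out-of-range cells become missing with a counted
  warning; absent required columns and duplicate respondent ids are hard
  errors.
* Percentages print to one decimal with half-up rounding, matching the
  published table style; serialized statistics carry six significant
  digits.
* EM starts from complete-case moments (ridge-repaired if not positive
  definite); a row with every goal missing imputes at the estimated mean
  with a warning.
* The ICC denominator can be zero only when there is neither
  between-subject variance nor error; that degenerate table is defined as
  1, and estimates are clipped below at -1.
* Ties in the c-statistic count one half via average ranks, which equals
  exhaustive pair enumeration (property-tested up to n = 200).
* All randomness flows through one seeded Mersenne-Twister stream;
  cohorts record the seed, generator version and RNG in their provenance,
  and identical seeds give byte-identical audit bundles.

## Problem sizes

The packaged experiments run at the study's own sizes: 440/88/35
respondents per cohort, 383 analyzable patients in the treatment model,
100 retest pairs, and 20-seed Monte-Carlo averages for calibrated
summaries (50 seeds for item-profile spot checks; reliability recovery
uses 300 pairs by 50 replicates). These match the published design; they
are also small enough that the full suite and the acceptance script run
comfortably on a laptop.

## Known limitations

* The concordance score is in-sample; it describes fit, not prospective
  prediction, and small cohorts will overstate it.
* EM assumes joint normality of ratings that are in truth discrete and
  heaped at the scale ends; the closed-form and recovery tests show the
  conditional means behave, but imputation quality on real data depends on
  how far those ratings depart from ellipticity.
* With 10.9% missingness concentrated among lumpectomy patients, goal
  imputation from goals alone is slightly biased toward the overall mean
  for that arm; the published analysis shares this property.
* The three-item deletion story is reproduced structurally (two easy, one
  reverse-keyed), but which real items were deleted, and on whose
  responses the easiness threshold was judged, is not published.
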