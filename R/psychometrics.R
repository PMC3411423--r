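#' Reliability, validity and feasibility evaluation
#'
#' Test-retest reliability is summarized with the intraclass correlation
#' coefficient, in the two-way random-effects, absolute-agreement,
#' single-measurement form, the standard choice for test-retest designs (the
#' source analysis plan says only "ICC"; the form is documented here as an
#' interpretation). Validity is assessed through the pre-specified
#' hypothesis battery: content (provider coverage ratings, patient top-three
#' goal selections), discriminant (group ANOVA with planned comparisons,
#' per-goal one-sided t-tests, preference gradient on model probabilities)
#' and predictive (confidence and regret by concordance status). Feasibility
#' covers per-item missingness and completion time. Planned contrasts use a
#' per-contrast alpha of 0.05 with no multiplicity adjustment, as none was
#' pre-specified; this is flagged in the report.
#'
#' @name psychometrics
NULL

#' Intraclass correlation coefficient (two-way random, absolute agreement,
#' single measurement)
#'
#' Computed from the two-way ANOVA mean squares of an n-subject-by-two-wave
#' table: with rows (subjects) mean square MSR, columns (waves) MSC and
#' residual MSE, ICC = (MSR - MSE) / (MSR + MSE + 2 (MSC - MSE) / n).
#' Incomplete pairs are dropped (count attached as attribute
#' `"n_dropped"`); the value is clipped below at -1. A degenerate table with
#' no between-subject variance and no error is defined as 1.
#'
#' @param test,retest paired measurement vectors.
#' @return ICC value in \[-1, 1\].
#' @export
icc <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  ok <- !is.na(test) & !is.na(retest)
  x <- cbind(test[ok], retest[ok])
  n <- nrow(x)
  if (n < 3L) stop("at least 3 complete pairs are required (got ", n, ")")
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  val <- if (denom <= 0) {
    if (msr - mse == 0) 1 else -1
  } else (msr - mse) / denom
  structure(max(val, -1), n_dropped = sum(!ok))
}

# one-sided p for a Welch t-test of greater-mean in the stated direction
welch_one_sided <- function(x_hi, x_lo) {
  if (sum(!is.na(x_hi)) < 2L || sum(!is.na(x_lo)) < 2L)
    return(c(diff = NA_real_, p = NA_real_))
  tt <- stats::t.test(x_hi, x_lo, alternative = "greater")
  c(diff = unname(diff(rev(tt$estimate))), p = tt$p.value)
}

#' Test-retest reliability report
#'
#' ICCs for the full knowledge score, the screener score and each goal
#' rating, over test/retest pairs linked by respondent id; each measure
#' drops its incomplete pairs listwise. Values are flagged against the a
#' priori 0.7 target.
#'
#' @param cohort a `dqi_cohort` containing both waves (or a test-wave cohort
#'   if `retest` supplies the retest records).
#' @param retest optional separate `dqi_cohort` holding the retest wave.
#' @return data.frame with `measure`, `icc`, `n_pairs`, `meets_target`.
#' @export
retest_report <- function(cohort, retest = NULL) {
  rec <- cohort$records
  if (!is.null(retest)) rec <- rbind(rec, retest$records)
  pat <- rec[rec$group == "patient", , drop = FALSE]
  t1 <- pat[pat$wave == "test", , drop = FALSE]
  t2 <- pat[pat$wave == "retest", , drop = FALSE]
  if (nrow(t2) == 0L) stop("no retest records found")
  common <- intersect(t1$respondent_id, t2$respondent_id)
  if (length(common) == 0L) stop("no linked test/retest pairs")
  t1 <- t1[match(common, t1$respondent_id), , drop = FALSE]
  t2 <- t2[match(common, t2$respondent_id), , drop = FALSE]

  measures <- list(
    knowledge_full = list(score_records(t1, cohort$item_bank, "reduced"),
                          score_records(t2, cohort$item_bank, "reduced")),
    knowledge_screener = list(score_records(t1, cohort$item_bank, "screener"),
                              score_records(t2, cohort$item_bank, "screener")))
  for (g in cohort$goals$goal_id) {
    col <- paste0("g_", g)
    measures[[g]] <- list(t1[[col]], t2[[col]])
  }
  out <- do.call(rbind, lapply(names(measures), function(m) {
    a <- measures[[m]][[1]]; b <- measures[[m]][[2]]
    ok <- sum(!is.na(a) & !is.na(b))
    val <- if (ok >= 3L) as.numeric(icc(a, b)) else NA_real_
    data.frame(measure = m, icc = val, n_pairs = ok,
               meets_target = !is.na(val) & val > 0.7,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Content validity report
#'
#' Knowledge: percentage of providers rating the item set as covering the
#' key facts very or extremely well (rating 3-4 on the 1-4 scale), against
#' the 70% target. Goals: percentage of patients placing each goal in their
#' top three, overall and by surgery arm, against the 20% target.
#'
#' @param cohort a `dqi_cohort`.
#' @return a `dqi_content_validity` list with `provider_coverage` and
#'   `goal_top3` tables.
#' @export
content_validity <- function(cohort) {
  rec <- cohort$records[cohort$records$wave == "test", , drop = FALSE]
  prov <- rec[rec$group == "provider", , drop = FALSE]
  cov_pct <- if (nrow(prov) && "coverage_rating" %in% names(prov))
    100 * mean(prov$coverage_rating >= 3, na.rm = TRUE) else NA_real_
  provider_coverage <- data.frame(pct_very_or_extremely = cov_pct,
                                  target = 70, pass = !is.na(cov_pct) & cov_pct > 70)

  pat <- rec[rec$group == "patient", , drop = FALSE]
  top3 <- as.matrix(pat[, c("top3_1", "top3_2", "top3_3"), drop = FALSE])
  arm <- ifelse(pat$treatment %in% c("mastectomy", "lumpectomy"),
                pat$treatment, NA)
  pct_sel <- function(rows) {
    if (!length(rows)) return(rep(NA_real_, nrow(cohort$goals)))
    vapply(cohort$goals$goal_id, function(g)
      100 * mean(apply(top3[rows, , drop = FALSE] == g, 1, any, na.rm = TRUE)),
      numeric(1))
  }
  goal_top3 <- data.frame(
    goal_id = cohort$goals$goal_id,
    overall_pct = pct_sel(seq_len(nrow(pat))),
    mastectomy_pct = pct_sel(which(!is.na(arm) & arm == "mastectomy")),
    lumpectomy_pct = pct_sel(which(!is.na(arm) & arm == "lumpectomy")),
    target = 20, stringsAsFactors = FALSE)
  goal_top3$pass <- !is.na(goal_top3$overall_pct) & goal_top3$overall_pct >= 20
  structure(list(provider_coverage = provider_coverage, goal_top3 = goal_top3),
            class = "dqi_content_validity")
}

# planned comparison using the one-way ANOVA pooled error term, one-sided
planned_contrast <- function(values, groups, hi, lo) {
  present <- c(hi, lo) %in% groups
  if (!all(present)) return(c(diff = NA_real_, t = NA_real_, p = NA_real_))
  fit <- stats::aov(values ~ factor(groups))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  df_e <- summary(fit)[[1]]["Residuals", "Df"]
  m <- tapply(values, groups, mean, na.rm = TRUE)
  n <- tapply(!is.na(values), groups, sum)
  d <- m[[hi]] - m[[lo]]
  se <- sqrt(mse * (1 / n[[hi]] + 1 / n[[lo]]))
  tval <- d / se
  c(diff = d, t = tval, p = stats::pt(tval, df_e, lower.tail = FALSE))
}

#' Discriminant validity report
#'
#' Knowledge: one-way ANOVA of the score over provider/patient/control with
#' planned one-sided comparisons (providers above patients; patients above
#' controls). Goals: per-goal one-sided Welch t-tests of the rating by
#' surgery received, in the direction declared by the goal bank.
#'
#' @param scoreset a `dqi_scoreset` (see [score_cohort()]).
#' @param cohort the `dqi_cohort` the scores came from.
#' @return a `dqi_discriminant` list: `anova_p`, `contrasts` table and
#'   `goal_tests` table.
#' @export
discriminant_validity <- function(scoreset, cohort) {
  s <- scoreset$scores
  s <- s[s$wave == "test" & !is.na(s$score), , drop = FALSE]
  if (length(unique(s$group)) < 2L) stop("need scores for at least 2 groups")
  anova_p <- summary(stats::aov(score ~ factor(group), data = s))[[1]][1, "Pr(>F)"]
  contrasts <- rbind(
    provider_gt_patient = planned_contrast(s$score, s$group, "provider", "patient"),
    patient_gt_control = planned_contrast(s$score, s$group, "patient", "control"))
  contrasts <- data.frame(contrast = rownames(contrasts), contrasts,
                          row.names = NULL, stringsAsFactors = FALSE)

  pat <- patients_test(cohort)
  mastq <- pat$treatment == "mastectomy"
  lumpq <- pat$treatment == "lumpectomy"
  goal_tests <- do.call(rbind, lapply(seq_len(nrow(cohort$goals)), function(i) {
    g <- cohort$goals[i, ]
    x <- pat[[paste0("g_", g$goal_id)]]
    if (g$expected_direction == "toward_mastectomy")
      res <- welch_one_sided(x[mastq], x[lumpq])
    else
      res <- welch_one_sided(x[lumpq], x[mastq])
    data.frame(goal_id = g$goal_id, direction = g$expected_direction,
               mean_mastectomy = mean(x[mastq], na.rm = TRUE),
               mean_lumpectomy = mean(x[lumpq], na.rm = TRUE),
               diff_expected_direction = unname(res["diff"]),
               p_one_sided = unname(res["p"]), stringsAsFactors = FALSE)
  }))
  structure(list(anova_p = anova_p, contrasts = contrasts,
                 goal_tests = goal_tests,
                 alpha_note = "per-contrast alpha 0.05, no multiplicity adjustment"),
            class = "dqi_discriminant")
}

#' Preference gradient on model-predicted probabilities
#'
#' Patients who preferred mastectomy should carry higher model-predicted
#' probabilities of mastectomy than those who were unsure, who in turn
#' should exceed those preferring lumpectomy with radiation: group means,
#' one-way ANOVA, and ordered planned comparisons.
#'
#' @param model a `dqi_treatment_model`.
#' @param records the analyzable patient records the model was fitted on
#'   (supplies `preference`).
#' @return a `dqi_preference_gradient` list.
#' @export
preference_gradient <- function(model, records) {
  stopifnot(nrow(records) == length(model$p))
  pref <- records$preference
  keep <- !is.na(pref) & pref %in% c("mastectomy", "not_sure", "lumpectomy_radiation")
  p <- model$p[keep]; pref <- pref[keep]
  if (length(unique(pref)) < 2L)
    stop("fewer than 2 preference levels present")
  means <- tapply(p, pref, mean)
  anova_p <- summary(stats::aov(p ~ factor(pref)))[[1]][1, "Pr(>F)"]
  contrasts <- rbind(
    mastectomy_gt_unsure = planned_contrast(p, pref, "mastectomy", "not_sure"),
    unsure_gt_lumpectomy = planned_contrast(p, pref, "not_sure", "lumpectomy_radiation"))
  contrasts <- data.frame(contrast = rownames(contrasts), contrasts,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(means = means, n = table(pref), anova_p = anova_p,
                 contrasts = contrasts),
            class = "dqi_preference_gradient")
}

#' Predictive validity of the concordance classification
#'
#' Compares decision confidence (two-sided Welch t-test) and willingness to
#' make the same choice again (regret dichotomized as definitely/probably
#' yes vs the rest; chi-square) between concordant and discordant patients.
#'
#' @param concordance a `dqi_concordance`.
#' @param records the analyzable patient records (supplies `confidence` and
#'   `regret`).
#' @return a `dqi_predictive` list; tests are skipped with a note when one
#'   concordance class is empty.
#' @export
predictive_validity <- function(concordance, records) {
  m <- match(concordance$per_patient$respondent_id, records$respondent_id)
  conc <- concordance$per_patient$concordant
  conf <- records$confidence[m]
  same_again <- records$regret[m] %in% c("definitely_yes", "probably_yes")
  same_again[is.na(records$regret[m])] <- NA
  note <- NULL
  if (length(unique(conc)) < 2L) {
    note <- "one concordance class empty; tests skipped"
    conf_test <- list(means = tapply(conf, conc, mean, na.rm = TRUE), p = NA_real_)
    regret_test <- list(pct_same_again = tapply(100 * same_again, conc, mean,
                                                na.rm = TRUE), p = NA_real_)
  } else {
    tt <- stats::t.test(conf[conc], conf[!conc])
    conf_test <- list(means = c(concordant = mean(conf[conc], na.rm = TRUE),
                                discordant = mean(conf[!conc], na.rm = TRUE)),
                      p = tt$p.value)
    tab <- table(conc, same_again)
    p_chi <- if (all(dim(tab) == c(2L, 2L)))
      stats::chisq.test(tab, correct = FALSE)$p.value else NA_real_
    regret_test <- list(
      pct_same_again = c(concordant = 100 * mean(same_again[conc], na.rm = TRUE),
                         discordant = 100 * mean(same_again[!conc], na.rm = TRUE)),
      p = p_chi)
  }
  structure(list(confidence = conf_test, regret = regret_test, note = note),
            class = "dqi_predictive")
}

#' Acceptability and feasibility report
#'
#' Per-item and per-goal missingness percentages with the over-5% offender
#' list, and completion-time summaries with a one-way ANOVA over the three
#' education levels.
#'
#' @param cohort a `dqi_cohort`.
#' @return a `dqi_feasibility` list.
#' @export
feasibility_report <- function(cohort) {
  pat <- patients_test(cohort)
  test <- cohort$records[cohort$records$wave == "test", , drop = FALSE]
  pt <- bank_parts(cohort$item_bank)
  item_missing <- data.frame(
    field = pt$part_id,
    missing_pct = vapply(pt$part_id, function(col)
      100 * mean(is.na(test[[col]])), numeric(1)),
    type = "knowledge", row.names = NULL, stringsAsFactors = FALSE)
  gcols <- goal_cols(cohort$goals)
  goal_missing <- data.frame(
    field = gcols,
    missing_pct = vapply(gcols, function(col)
      100 * mean(is.na(pat[[col]])), numeric(1)),
    type = "goal", row.names = NULL, stringsAsFactors = FALSE)
  missing <- rbind(item_missing, goal_missing)
  offenders <- missing$field[missing$missing_pct > 5]

  tm <- pat$completion_minutes
  edu <- factor(pat$education, EDUCATION_LEVELS)
  time_anova_p <- if (nlevels(droplevels(edu[!is.na(tm)])) >= 2L)
    summary(stats::aov(tm ~ edu))[[1]][1, "Pr(>F)"] else NA_real_
  structure(list(
    missing = missing,
    knowledge_missing_mean = mean(item_missing$missing_pct),
    goal_missing_median = stats::median(goal_missing$missing_pct),
    offenders = offenders,
    completion = list(mean = mean(tm, na.rm = TRUE),
                      range = range(tm, na.rm = TRUE),
                      by_education = tapply(tm, edu, mean, na.rm = TRUE),
                      anova_p = time_anova_p)),
    class = "dqi_feasibility")
}
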