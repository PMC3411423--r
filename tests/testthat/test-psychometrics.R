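test_that("ICC matches the explicit ANOVA decomposition", {
  # identical vectors with between-subject spread
  expect_equal(as.numeric(icc(c(1, 3, 5, 9), c(1, 3, 5, 9))), 1)
  # hand table, against the mean-squares oracle
  x <- c(1, 3, 5, 7); y <- c(2, 3, 4, 8)
  expect_equal(as.numeric(icc(x, y)), oracle_icc(x, y))
  expect_equal(oracle_icc(x, y), 12.666667 / 13.416667, tolerance = 1e-6)
  # symmetry in wave labels
  expect_equal(as.numeric(icc(x, y)), as.numeric(icc(y, x)))
  # independent noise -> near zero
  set.seed(1)
  a <- rnorm(500); b <- rnorm(500)
  expect_lt(abs(as.numeric(icc(a, b))), 0.1)
  # degenerate: no between-subject variance, no error
  expect_equal(as.numeric(icc(rep(2, 5), rep(2, 5))), 1)
  expect_error(icc(1:2, 2:1), "at least 3")
  # incomplete pairs dropped and counted
  v <- icc(c(1, 3, 5, 7, NA), c(2, 3, 4, 8, 1))
  expect_equal(attr(v, "n_dropped"), 1L)
  expect_equal(as.numeric(v), oracle_icc(x, y))
})

test_that("ICC estimator recovers true reliability", {
  set.seed(2)
  for (rho in c(0.3, 0.6, 0.9)) {
    est <- replicate(50, {
      subj <- rnorm(300, sd = sqrt(rho))
      as.numeric(icc(subj + rnorm(300, sd = sqrt(1 - rho)),
                     subj + rnorm(300, sd = sqrt(1 - rho))))
    })
    expect_lt(abs(mean(est) - rho), 0.04)
  }
})

test_that("one-sided p halves the two-sided p in the expected direction", {
  set.seed(3)
  x <- rnorm(40, 1); y <- rnorm(35, 0)
  one <- bcsdqi:::welch_one_sided(x, y)
  two <- t.test(x, y)
  expect_equal(unname(one["p"]), two$p.value / 2)
  # and directly against the t CDF
  expect_equal(unname(one["p"]),
               pt(two$statistic, two$parameter, lower.tail = FALSE),
               ignore_attr = TRUE)
})

test_that("content validity applies the 70% and 20% cutoffs", {
  bank <- tiny_bank()
  prov <- blank_records(88, bank)
  prov$respondent_id <- paste0("D", 1:88)
  prov$group <- "provider"
  prov$coverage_rating <- rep(c(4, 3, 2, 1), c(30, 37, 14, 7))  # 67/88
  pat <- blank_records(200, bank)
  pat$treatment <- rep(c("lumpectomy", "mastectomy"), each = 100)
  # hassle goal in the top 3 for 19% of lumpectomy, 12% of mastectomy patients
  pat$top3_1 <- "avoid_recurrence"
  pat$top3_2 <- c(rep("radiation_hassle", 19), rep("keep_breast", 81),
                  rep("radiation_hassle", 12), rep("remove_breast", 88))
  cv <- content_validity(tiny_cohort(rbind(prov, pat), bank))
  expect_equal(cv$provider_coverage$pct_very_or_extremely, 100 * 67 / 88)
  expect_true(cv$provider_coverage$pass)
  gt <- cv$goal_top3
  hassle <- gt[gt$goal_id == "radiation_hassle", ]
  expect_equal(hassle$lumpectomy_pct, 19)
  expect_equal(hassle$mastectomy_pct, 12)
  expect_false(hassle$pass)
  expect_equal(gt$overall_pct[gt$goal_id == "avoid_recurrence"], 100)
  expect_true(gt$pass[gt$goal_id == "avoid_recurrence"])
})

test_that("discriminant contrasts detect group differences and not noise", {
  set.seed(4)
  mk_scores <- function(pat, prov, ctrl) {
    data.frame(
      respondent_id = as.character(seq_len(length(pat) + length(prov) + length(ctrl))),
      group = rep(c("patient", "provider", "control"),
                  c(length(pat), length(prov), length(ctrl))),
      wave = "test", score = c(pat, prov, ctrl), stringsAsFactors = FALSE)
  }
  co <- generate_cohort(small_config(80L, 30L, 25L), seed = 8)
  ss <- list(scores = mk_scores(rnorm(440, 52.7, 21.8), rnorm(88, 87.7, 10),
                                rnorm(35, 49.3, 20)), item_set = "reduced")
  class(ss) <- "dqi_scoreset"
  d <- discriminant_validity(ss, co)
  expect_lt(d$anova_p, 0.001)
  ctr <- d$contrasts
  expect_lt(ctr$p[ctr$contrast == "provider_gt_patient"], 0.001)
  expect_gt(ctr$diff[ctr$contrast == "provider_gt_patient"], 25)

  # identical distributions -> non-significant contrasts (uniform p)
  ss0 <- ss
  ss0$scores$score <- rnorm(nrow(ss0$scores), 50, 10)
  d0 <- discriminant_validity(ss0, co)
  expect_gt(d0$anova_p, 0.001)
})

test_that("goal direction tests follow the declared expected direction", {
  bank <- tiny_bank()
  set.seed(5)
  pat <- blank_records(300, bank)
  pat$treatment <- rep(c("mastectomy", "lumpectomy"), c(90, 210))
  pat$g_avoid_radiation <- pmin(10, pmax(0, round(
    c(rnorm(90, 5.1, 3), rnorm(210, 2.1, 2.5)))))
  pat$g_keep_breast <- pmin(10, pmax(0, round(
    c(rnorm(90, 3.0, 3), rnorm(210, 6.6, 3)))))
  pat$q1 <- "1"
  prov <- blank_records(40, bank)
  prov$respondent_id <- paste0("D", 1:40)
  prov$group <- "provider"
  prov$q1 <- "2"
  ss <- score_cohort(tiny_cohort(rbind(pat, prov), bank), "screener")
  d <- discriminant_validity(ss, tiny_cohort(pat, bank))
  gt <- d$goal_tests
  expect_lt(gt$p_one_sided[gt$goal_id == "avoid_radiation"], 1e-4)
  expect_lt(gt$p_one_sided[gt$goal_id == "keep_breast"], 1e-4)
  expect_gt(gt$diff_expected_direction[gt$goal_id == "keep_breast"], 0)
})

test_that("the preference gradient orders predicted probabilities", {
  set.seed(6)
  n <- 300
  p <- runif(n)
  pref <- ifelse(p > 0.6 & runif(n) < 0.8, "mastectomy",
                 ifelse(p < 0.35, "lumpectomy_radiation", "not_sure"))
  model <- structure(list(p = p, y = p > 0.5,
                          respondent_id = as.character(1:n)),
                     class = "dqi_treatment_model")
  rec <- data.frame(respondent_id = as.character(1:n), preference = pref,
                    stringsAsFactors = FALSE)
  g <- preference_gradient(model, rec)
  expect_gt(g$means[["mastectomy"]], g$means[["not_sure"]])
  expect_gt(g$means[["not_sure"]], g$means[["lumpectomy_radiation"]])
  expect_lt(g$anova_p, 1e-6)

  # preference unrelated to p -> non-significant
  rec0 <- rec
  rec0$preference <- sample(pref)
  expect_gt(preference_gradient(model, rec0)$anova_p, 0.001)

  rec1 <- rec
  rec1$preference <- "mastectomy"
  expect_error(preference_gradient(model, rec1), "2 preference levels")
})

test_that("predictive validity detects injected effects and not null ones", {
  set.seed(7)
  n <- 300
  conc <- runif(n) < 0.85
  rec <- data.frame(
    respondent_id = as.character(1:n),
    confidence = pmin(10, pmax(0, round(rnorm(n, 9.1, 1.4)))),
    regret = sample(c("definitely_yes", "probably_yes", "not_sure",
                      "probably_no"), n, TRUE, c(0.55, 0.33, 0.08, 0.04)),
    stringsAsFactors = FALSE)
  concordance <- structure(list(per_patient = data.frame(
    respondent_id = rec$respondent_id, concordant = conc,
    stringsAsFactors = FALSE)), class = "dqi_concordance")
  null_res <- predictive_validity(concordance, rec)
  expect_gt(null_res$confidence$p, 0.001)
  expect_gt(null_res$regret$p, 0.001)

  rec2 <- rec
  rec2$confidence <- pmin(10, rec$confidence + ifelse(conc, 0, -3))
  shifted <- predictive_validity(concordance, rec2)
  expect_lt(shifted$confidence$p, 1e-6)
  expect_gt(shifted$confidence$means[["concordant"]],
            shifted$confidence$means[["discordant"]])

  # one class empty -> skipped with note
  conc_all <- structure(list(per_patient = data.frame(
    respondent_id = rec$respondent_id, concordant = TRUE,
    stringsAsFactors = FALSE)), class = "dqi_concordance")
  res_all <- predictive_validity(conc_all, rec)
  expect_match(res_all$note, "skipped")
  expect_true(is.na(res_all$confidence$p))
})

test_that("feasibility reports missingness offenders and completion time", {
  bank <- tiny_bank()
  pat <- blank_records(400, bank)
  pat$q1 <- "2"; pat$q2 <- "1"; pat$q3 <- "85"; pat$q4a <- "1"; pat$q4b <- "3"
  for (g in bcsdqi:::goal_cols(default_goal_bank())) pat[[g]] <- 5
  pat$g_remove_breast[1:44] <- NA          # 11% missing
  pat$education <- rep(c("hs_or_less", "some_college", "college_plus"),
                       c(50, 100, 250))
  set.seed(8)
  pat$completion_minutes <- round(pmax(1.4, rnorm(
    400, c(hs_or_less = 6.8, some_college = 6.4,
           college_plus = 5.3)[pat$education], 1.5)), 1)
  f <- feasibility_report(tiny_cohort(pat, bank))
  expect_identical(f$offenders, "g_remove_breast")
  expect_equal(f$missing$missing_pct[f$missing$field == "g_remove_breast"], 11)
  expect_lt(f$completion$anova_p, 0.001)
  expect_equal(unname(f$completion$by_education["hs_or_less"]), 6.8,
               tolerance = 0.5)

  # zero-missingness cohort -> no offenders
  pat$g_remove_breast <- 5
  f0 <- feasibility_report(tiny_cohort(pat, bank))
  expect_length(f0$offenders, 0)
})

test_that("every pre-specified validity hypothesis appears exactly once", {
  co <- generate_cohort(small_config(150L, 40L, 30L), seed = 9)
  rt <- generate_retest(co, small_config(150L, 40L, 30L), seed = 10)
  audit <- run_audit(cohort = co, retest = rt)
  psy <- audit$psychometrics
  # 1a provider coverage, 1b goal top-3
  expect_equal(nrow(psy$content$provider_coverage), 1L)
  expect_equal(nrow(psy$content$goal_top3), nrow(co$goals))
  # 2a group contrasts (one per planned comparison)
  expect_equal(psy$discriminant$contrasts$contrast,
               c("provider_gt_patient", "patient_gt_control"))
  # 2b one one-sided test per goal
  expect_equal(psy$discriminant$goal_tests$goal_id, co$goals$goal_id)
  # 2c preference gradient present with both ordered comparisons
  expect_equal(psy$preference$contrasts$contrast,
               c("mastectomy_gt_unsure", "unsure_gt_lumpectomy"))
  # 3a confidence and regret each tested once
  expect_named(psy$predictive$confidence, c("means", "p"))
  expect_named(psy$predictive$regret, c("pct_same_again", "p"))
})
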