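test_that("exclusions remove clinically ineligible patients only", {
  cfg <- small_config(200L)
  co <- generate_cohort(cfg, seed = 3)
  ana <- apply_exclusions(co)
  ex <- attr(ana, "exclusions")
  expect_equal(nrow(ana) + sum(ex), sum(co$records$group == "patient"))
  expect_false(any(ana$treatment == "lumpectomy_then_mastectomy"))
  expect_true(all(ana$treatment %in% c("mastectomy", "lumpectomy")))

  # no exclusions present -> identity
  keep <- ana
  co2 <- tiny_cohort(keep, co$item_bank, co$goals)
  ana2 <- apply_exclusions(co2)
  expect_equal(nrow(ana2), nrow(keep))

  # everyone excluded -> error
  allx <- patients_test_records <- co$records[co$records$group == "patient" &
                                                co$records$wave == "test", ]
  allx$treatment <- "lumpectomy_then_mastectomy"
  expect_error(apply_exclusions(tiny_cohort(allx, co$item_bank, co$goals)),
               "no analyzable")
})

test_that("EM leaves complete data at its sample moments", {
  set.seed(1)
  x <- MASS::mvrnorm(200, mu = c(4, 6), Sigma = rbind(c(4, 1), c(1, 2)))
  colnames(x) <- c("a", "b")
  em <- em_impute_goals(x, clip = c(-Inf, Inf))
  expect_equal(em$completed, x)
  expect_equal(em$mu, colMeans(x), ignore_attr = TRUE)
  expect_equal(em$sigma, stats::cov(x) * (199 / 200), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("EM imputation matches the closed-form conditional mean", {
  # bivariate normal with one missing entry: the imputed value must equal
  # mu1 + s12/s22 (x2 - mu2) under the EM-estimated moments
  set.seed(2)
  n <- 400
  S <- rbind(c(4, 1.6), c(1.6, 2.25))
  x <- MASS::mvrnorm(n, mu = c(5, 5), Sigma = S)
  colnames(x) <- c("a", "b")
  xm <- x
  xm[1, 1] <- NA
  em <- em_impute_goals(xm, clip = c(-Inf, Inf))
  cond <- em$mu[1] + em$sigma[1, 2] / em$sigma[2, 2] * (x[1, 2] - em$mu[2])
  expect_equal(unname(em$completed[1, 1]), unname(cond), tolerance = 1e-4)
})

test_that("EM log-likelihood is monotone and beats mean imputation", {
  set.seed(3)
  S <- rbind(c(4, 2, 1), c(2, 4, 2), c(1, 2, 4))
  x <- MASS::mvrnorm(500, mu = c(5, 5, 5), Sigma = S)
  colnames(x) <- c("a", "b", "c")
  xm <- x
  holes <- matrix(runif(length(x)) < 0.05, nrow(x))
  holes[rowSums(holes) == 3, 1] <- FALSE  # keep one observed per row
  xm[holes] <- NA
  em <- em_impute_goals(xm, clip = c(-Inf, Inf))
  expect_true(all(diff(em$loglik) >= -1e-8))
  # observed entries never altered
  expect_equal(em$completed[!holes], x[!holes])
  rmse_em <- sqrt(mean((em$completed[holes] - x[holes])^2))
  colmean <- matrix(colMeans(xm, na.rm = TRUE), nrow(x), 3, byrow = TRUE)
  rmse_mean <- sqrt(mean((colmean[holes] - x[holes])^2))
  expect_lt(rmse_em, rmse_mean)

  # all-missing row warns and lands at the mean, clipped entries in range
  xm2 <- x[1:50, ]
  xm2[1, ] <- NA
  expect_warning(em2 <- em_impute_goals(xm2), "all goals missing")
  expect_true(all(em2$completed[1, ] >= 0 & em2$completed[1, ] <= 10))
})

test_that("c-statistic equals brute-force pair counting", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  # worked example: cases 0.9/0.4/0.6 vs controls 0.3/0.6
  p <- c(0.9, 0.4, 0.6, 0.3, 0.6)
  y <- c(1, 1, 1, 0, 0)
  expect_equal(oracle_cstat(p, y), 4.5 / 6)
  expect_equal(c_statistic(p, y), 4.5 / 6)
  expect_error(c_statistic(c(0.1, 0.2), c(1, 1)), "case and one control")

  set.seed(4)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    p <- round(runif(n), sample(c(1, 2, 3), 1))  # force some ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(p, y), oracle_cstat(p, y))
  }
})

test_that("c-statistic agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  p <- runif(300)
  y <- rbinom(300, 1, plogis(3 * (p - 0.5)))
  expect_equal(c_statistic(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("the logistic fit recovers a null model and flags separation", {
  set.seed(6)
  n <- 400
  g <- matrix(round(runif(n * 3, 0, 10)), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  rec <- data.frame(respondent_id = as.character(seq_len(n)),
                    treatment = ifelse(runif(n) < 0.4, "mastectomy", "lumpectomy"),
                    stage = sample(c("I", "II"), n, TRUE),
                    stringsAsFactors = FALSE)
  fit <- fit_treatment_model(rec, g)
  ors <- fit$coefficients[fit$coefficients$term %in% c("a", "b", "c"), ]
  expect_true(all(abs(ors$or - 1) < 0.15))
  expect_true(all(ors$or_lo < 1 & ors$or_hi > 1))

  # perfectly separated toy data
  rec2 <- data.frame(respondent_id = as.character(1:30),
                     treatment = rep(c("mastectomy", "lumpectomy"), each = 15),
                     stage = "I", stringsAsFactors = FALSE)
  g2 <- cbind(a = c(rep(9, 15), rep(1, 15)), b = round(runif(30, 0, 10)))
  expect_warning(fit_treatment_model(rec2, g2, include_stage = FALSE),
                 "separation")

  rec3 <- rec2
  rec3$treatment <- "mastectomy"
  expect_error(fit_treatment_model(rec3, g2), "constant")
})

test_that("concordance classification uses the inclusive 0.5 boundary", {
  fake_model <- structure(list(
    p = c(0.7, 0.5, 0.49, 0.2),
    y = c(TRUE, TRUE, TRUE, FALSE),
    respondent_id = as.character(1:4)), class = "dqi_treatment_model")
  res <- classify_concordance(fake_model)
  expect_equal(res$per_patient$concordant, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$overall_pct, 75)
  expect_equal(res$by_arm[["mastectomy"]], 100 * 2 / 3)
  expect_equal(res$by_arm[["lumpectomy"]], 100)

  # invariant under patient reordering
  perm <- c(3, 1, 4, 2)
  fake2 <- structure(list(p = fake_model$p[perm], y = fake_model$y[perm],
                          respondent_id = fake_model$respondent_id[perm]),
                     class = "dqi_treatment_model")
  expect_equal(classify_concordance(fake2)$overall_pct, res$overall_pct)
})

test_that("univariate screen reproduces the published stage chi-square", {
  # stage II among mastectomy 59/111, among lumpectomy 89/272
  rec <- data.frame(
    respondent_id = as.character(1:383),
    treatment = rep(c("mastectomy", "lumpectomy"), c(111, 272)),
    stage = c(rep(c("II", "I"), c(59, 52)), rep(c("II", "I"), c(89, 183))),
    stringsAsFactors = FALSE)
  g <- matrix(5, 383, 1, dimnames = list(NULL, "keep_breast"))
  tab <- univariate_screen(rec, g)
  p_stage <- tab$p[tab$factor == "stage_II"]
  expect_equal(round(p_stage, 4), 2e-04)
  expect_equal(tab$mastectomy[tab$factor == "stage_II"], 100 * 59 / 111)

  # identical goal distributions -> near-zero mean difference
  set.seed(7)
  g2 <- matrix(round(runif(383, 0, 10)), 383, 1,
               dimnames = list(NULL, "keep_breast"))
  tab2 <- univariate_screen(rec, g2)
  row <- tab2[tab2$factor == "keep_breast", ]
  expect_lt(abs(row$mastectomy - row$lumpectomy), 1)
  expect_gt(row$p, 0.01)
})
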