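#' Goals-to-treatment concordance
#'
#' The concordance score asks whether patients received the surgery their
#' stated goals predict. Missing goal ratings are imputed under a joint
#' multivariate-normal model by expectation-maximization; a multivariable
#' logistic regression of treatment (mastectomy vs lumpectomy) on disease
#' stage and the goal ratings is fitted in-sample; each patient is classified
#' concordant when the model-predicted probability of mastectomy is at least
#' 0.5 and mastectomy was received, or below 0.5 and lumpectomy was
#' received. The score is deliberately an in-sample goodness-of-fit summary:
#' it measures how well treatments track goals in the audited group, not
#' out-of-sample prediction.
#'
#' @name concordance
NULL

#' Restrict a cohort to concordance-analyzable patients
#'
#' Patients who had lumpectomy followed by mastectomy are excluded (their
#' treatment was clinically forced, so a goals mismatch is uninformative), as
#' are patients with no definitive surgery recorded (the model outcome is
#' binary). Each respondent must also carry at least one observed
#' concordance-model goal rating for the imputation step.
#'
#' @param cohort a `dqi_cohort`.
#' @return records data.frame of analyzable patients, with attribute
#'   `"exclusions"` (named counts).
#' @export
apply_exclusions <- function(cohort) {
  pat <- patients_test(cohort)
  gm <- goal_matrix(pat, cohort$goals)
  no_goals <- rowSums(!is.na(gm)) == 0L
  ltm <- !is.na(pat$treatment) & pat$treatment == "lumpectomy_then_mastectomy"
  nonbinary <- is.na(pat$treatment) | pat$treatment == "none"
  keep <- !ltm & !nonbinary & !no_goals
  out <- pat[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no analyzable patients after exclusions")
  attr(out, "exclusions") <- c(
    lumpectomy_then_mastectomy = sum(ltm),
    no_definitive_surgery = sum(nonbinary & !ltm),
    no_observed_goals = sum(no_goals & !ltm & !nonbinary))
  out
}

#' EM imputation of goal ratings under joint normality
#'
#' Fits a multivariate-normal mean and covariance to a goal-rating matrix
#' with missing entries by expectation-maximization. The E-step replaces each
#' row's missing block with its conditional expectation given the observed
#' block and adds the conditional covariance to the second-moment
#' accumulator; the M-step re-estimates the mean and covariance from the
#' completed moments. The observed-data log-likelihood is checked to be
#' non-decreasing at every iteration. After convergence the imputed entries
#' are clipped to the 0-10 rating scale; observed entries are never altered.
#'
#' @param x numeric matrix (rows respondents, columns goals) with `NA` for
#'   missing; at least two columns.
#' @param tol convergence tolerance on the largest absolute parameter change
#'   (default 1e-6).
#' @param max_iter iteration cap (default 500); non-convergence is an error.
#' @param clip range imputed values are clipped to (default `c(0, 10)`).
#' @return a `dqi_em` list: `completed` matrix, `mu`, `sigma`, `n_iter`,
#'   `loglik` trace, and `imputed` logical matrix.
#' @export
em_impute_goals <- function(x, tol = 1e-6, max_iter = 500L, clip = c(0, 10)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  n <- nrow(x)
  if (p < 2L) stop("at least two goal columns are required")
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0L))
    warning(sum(rowSums(!miss) == 0L),
            " respondent(s) with all goals missing imputed at the estimated mean")

  mu <- colMeans(x, na.rm = TRUE)
  sigma <- stats::cov(x, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  if (inherits(try(chol(sigma), silent = TRUE), "try-error"))
    sigma <- sigma + diag(p) * (0.1 + abs(min(eigen(sigma, symmetric = TRUE,
                                                    only.values = TRUE)$values)))

  pattern <- apply(miss, 1, function(m) paste(as.integer(m), collapse = ""))
  rows_by_pattern <- split(seq_len(n), pattern)
  loglik <- numeric(0)

  obs_loglik <- function(mu, sigma) {
    ll <- 0
    for (rows in rows_by_pattern) {
      o <- which(!miss[rows[1], ])
      if (length(o) == 0L) next
      ll <- ll + sum(logdmvnorm(x[rows, o, drop = FALSE], mu[o],
                                sigma[o, o, drop = FALSE]))
    }
    ll
  }

  completed <- x
  for (iter in seq_len(max_iter)) {
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    for (rows in rows_by_pattern) {
      m <- which(miss[rows[1], ])
      o <- which(!miss[rows[1], ])
      xr <- x[rows, , drop = FALSE]
      if (length(m) == 0L) {
        t1 <- t1 + colSums(xr)
        t2 <- t2 + crossprod(xr)
        completed[rows, ] <- xr
        next
      }
      if (length(o) == 0L) {
        cond <- matrix(mu, length(rows), p, byrow = TRUE)
        v <- sigma
      } else {
        so_inv <- solve(sigma[o, o, drop = FALSE])
        beta <- sigma[m, o, drop = FALSE] %*% so_inv
        cond <- xr
        cond[, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          t(beta %*% (t(xr[, o, drop = FALSE]) - mu[o]))
        v <- matrix(0, p, p)
        v[m, m] <- sigma[m, m, drop = FALSE] -
          beta %*% sigma[o, m, drop = FALSE]
      }
      t1 <- t1 + colSums(cond)
      t2 <- t2 + crossprod(cond) + length(rows) * v
      completed[rows, ] <- cond
    }
    mu_new <- t1 / n
    sigma_new <- t2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2

    loglik <- c(loglik, obs_loglik(mu_new, sigma_new))
    if (length(loglik) > 1L &&
        loglik[length(loglik)] < loglik[length(loglik) - 1L] - 1e-8)
      stop("EM log-likelihood decreased at iteration ", iter,
           " (", loglik[length(loglik) - 1L], " -> ", loglik[length(loglik)], ")")

    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("EM did not converge within ", max_iter,
         " iterations; last parameter change ", signif(delta, 4),
         "; log-likelihood trace tail: ",
         paste(signif(utils::tail(loglik, 5), 8), collapse = ", "))

  completed[miss] <- pmin(pmax(completed[miss], clip[1]), clip[2])
  completed[!miss] <- x[!miss]
  structure(list(completed = completed, mu = mu, sigma = sigma,
                 n_iter = iter, loglik = loglik, imputed = miss),
            class = "dqi_em")
}

#' Fit the multivariable logistic treatment model
#'
#' Maximum-likelihood logistic regression of mastectomy (vs lumpectomy) on
#' stage II and the goal ratings, by iteratively reweighted least squares
#' (tolerance 1e-8, 100-iteration cap), with Wald 95% confidence intervals
#' on the odds ratios. The model includes all concordance-model goals, not
#' only the ones that reach significance.
#'
#' @param records analyzable patient records (see [apply_exclusions()]).
#' @param goal_values completed (imputed) goal matrix aligned with `records`.
#' @param include_stage add the stage II indicator (default TRUE).
#' @return a `dqi_treatment_model`: coefficient table with ORs and CIs,
#'   fitted probabilities `p`, `c_statistic`, outcome vector and fit
#'   metadata.
#' @export
fit_treatment_model <- function(records, goal_values, include_stage = TRUE) {
  y <- records$treatment == "mastectomy"
  if (length(unique(y)) < 2L)
    stop("treatment is constant; cannot fit the model")
  if (anyNA(goal_values))
    stop("goal_values contain missing entries; impute them first ",
         "(see em_impute_goals)")
  df <- as.data.frame(goal_values)
  if (include_stage) df$stage_II <- as.numeric(records$stage == "II")
  df$y <- as.numeric(y)
  n_par <- ncol(df)
  if (nrow(df) < 10 * n_par)
    warning("fewer than 10 observations per parameter (n = ", nrow(df),
            ", parameters = ", n_par, ")")
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- any(abs(beta) > 15)
  if (separated)
    warning("possible separation: a coefficient exceeds 15 in absolute value")
  coefs <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    or_lo = exp(unname(beta - 1.96 * se)),
    or_hi = exp(unname(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    row.names = NULL, stringsAsFactors = FALSE)
  p_hat <- stats::fitted(fit)
  structure(list(coefficients = coefs, p = unname(p_hat), y = y,
                 respondent_id = records$respondent_id,
                 c_statistic = c_statistic(p_hat, y),
                 converged = fit$converged, separated = separated,
                 n = nrow(df), include_stage = include_stage,
                 glm = fit),
            class = "dqi_treatment_model")
}

#' @export
print.dqi_treatment_model <- function(x, ...) {
  cat("Logistic treatment model (mastectomy vs lumpectomy), n = ", x$n,
      ", c = ", round_half_up(x$c_statistic, 2), "\n", sep = "")
  tab <- x$coefficients
  tab$or <- round_half_up(tab$or, 2)
  tab$or_lo <- round_half_up(tab$or_lo, 2)
  tab$or_hi <- round_half_up(tab$or_hi, 2)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "or", "or_lo", "or_hi", "p")], row.names = FALSE)
  invisible(x)
}

#' Rank-based c-statistic (area under the ROC curve)
#'
#' Proportion of case-control pairs in which the case carries the higher
#' predicted probability, ties counted one half; computed from average
#' ranks, equivalent to exhaustive pair enumeration.
#'
#' @param p predicted probabilities.
#' @param y outcomes (logical or 0/1); must contain both classes.
#' @return value in \[0, 1\].
#' @export
c_statistic <- function(p, y) {
  y <- as.logical(y)
  stopifnot(length(p) == length(y), !anyNA(p), !anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("c-statistic requires at least one case and one control")
  r <- rank(p)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify goal-treatment concordance
#'
#' A patient is concordant when the model-predicted probability of
#' mastectomy is at least 0.5 and mastectomy was received, or below 0.5 and
#' lumpectomy was received (the 0.5 boundary counts as predicted
#' mastectomy).
#'
#' @param model a fitted `dqi_treatment_model`.
#' @return a `dqi_concordance`: per-patient table, overall percentage and
#'   per-arm percentages.
#' @export
classify_concordance <- function(model) {
  stopifnot(inherits(model, "dqi_treatment_model"))
  predicted_mast <- model$p >= 0.5
  concordant <- predicted_mast == model$y
  per_patient <- data.frame(respondent_id = model$respondent_id,
                            p = model$p,
                            treatment = ifelse(model$y, "mastectomy", "lumpectomy"),
                            concordant = concordant,
                            stringsAsFactors = FALSE)
  structure(list(
    per_patient = per_patient,
    overall_pct = 100 * mean(concordant),
    by_arm = c(mastectomy = 100 * mean(concordant[model$y]),
               lumpectomy = 100 * mean(concordant[!model$y])),
    n = length(concordant)),
    class = "dqi_concordance")
}

#' @export
print.dqi_concordance <- function(x, ...) {
  cat("Concordance: ", round_half_up(x$overall_pct, 1), "% of ", x$n,
      " analyzable patients (mastectomy ",
      round_half_up(x$by_arm[["mastectomy"]], 1), "%, lumpectomy ",
      round_half_up(x$by_arm[["lumpectomy"]], 1), "%)\n", sep = "")
  invisible(x)
}

#' Univariate screen of treatment predictors
#'
#' Per-goal two-sample Welch t-tests of the rating by surgery received, and
#' a chi-square test (without continuity correction) for stage, with arm
#' means/percentages reported alongside.
#'
#' @param records analyzable patient records.
#' @param goal_values goal matrix aligned with `records` (imputed or
#'   observed; rows with `NA` are dropped per goal).
#' @return data.frame with one row per factor: arm summaries, test used and
#'   p-value.
#' @export
univariate_screen <- function(records, goal_values) {
  mast <- records$treatment == "mastectomy"
  rows <- list()
  if ("stage" %in% names(records) && !all(is.na(records$stage))) {
    tab <- table(factor(mast, c(TRUE, FALSE)),
                 factor(records$stage == "II", c(TRUE, FALSE)))
    p <- if (any(rowSums(tab) < 2)) NA_real_ else
      stats::chisq.test(tab, correct = FALSE)$p.value
    rows[["stage_II"]] <- data.frame(
      factor = "stage_II",
      mastectomy = 100 * mean(records$stage[mast] == "II", na.rm = TRUE),
      lumpectomy = 100 * mean(records$stage[!mast] == "II", na.rm = TRUE),
      test = "chi-square", p = p, stringsAsFactors = FALSE)
  }
  for (g in colnames(goal_values)) {
    x1 <- goal_values[mast, g]; x0 <- goal_values[!mast, g]
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    p <- if (length(x1) < 2L || length(x0) < 2L) NA_real_ else
      tryCatch(stats::t.test(x1, x0)$p.value, error = function(e) NA_real_)
    rows[[g]] <- data.frame(factor = g, mastectomy = mean(x1),
                            lumpectomy = mean(x0), test = "welch-t", p = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
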