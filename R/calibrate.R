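#' Generator calibration
#'
#' Tunes free generator parameters until Monte-Carlo estimates of named
#' summary statistics hit supplied targets. Each target names the statistic,
#' the value to hit, a tolerance, and the configuration parameter that
#' steers it (a dotted path into the configuration list, e.g.
#' `"free_item_shift.patient"`, `"treatment.intercept"`,
#' `"goal_mu.keep_breast"`, `"goal_wave_sd.keep_breast"`,
#' `"goal_sigma.keep_breast.remove_breast"`). Statistics are estimated by
#' generating cohorts over a block of seeds and running the relevant slice
#' of the analysis pipeline; parameters are updated by a damped secant rule
#' per coordinate until every target is inside its tolerance. Unreachable
#' targets error out with the worst offender after the iteration cap.
#'
#' @name calibration
NULL

cfg_get <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "goal_sigma" && length(parts) == 3L)
    return(config$goal_sigma[parts[2], parts[3]])
  x <- config
  for (p in parts) x <- x[[p]]
  x
}

cfg_set <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "goal_sigma" && length(parts) == 3L) {
    config$goal_sigma[parts[2], parts[3]] <- value
    config$goal_sigma[parts[3], parts[2]] <- value
    return(config)
  }
  if (length(parts) == 1L) config[[parts]] <- value
  else if (length(parts) == 2L) config[[parts[1]]][[parts[2]]] <- value
  else if (length(parts) == 3L) config[[parts[1]]][[parts[2]]][[parts[3]]] <- value
  else stop("unsupported parameter path: ", path)
  config
}

#' Monte-Carlo summary statistics of the generator
#'
#' Generates one cohort per seed (plus a retest wave when reliability
#' statistics are requested), runs the relevant slice of the analysis
#' pipeline, and returns the across-seed mean of each named statistic.
#' Available names include the group knowledge means/SD and gap, the
#' screener-full correlation, the keep-remove goal correlation, pipeline
#' quantities (`c_statistic`, `concordance_overall`,
#' `concordance_mastectomy`, `concordance_lumpectomy`,
#' `mastectomy_fraction`, `or_<term>`, `arm_mean_<goal>_<arm>`) and retest
#' reliabilities (`knowledge_icc`, `screener_icc`, `<goal>_icc`).
#'
#' @param config a `dqi_generator_config`.
#' @param stats character vector of statistic names.
#' @param seeds integer vector of seeds (one cohort each).
#' @param bank,goals instrument banks.
#' @return named numeric vector of Monte-Carlo means.
#' @export
generator_statistics <- function(config, stats, seeds,
                                 bank = default_item_bank(),
                                 goals = default_goal_bank()) {
  need_retest <- any(grepl("_icc$", stats))
  need_model <- any(stats %in% c("c_statistic", "concordance_overall",
                                 "concordance_mastectomy", "concordance_lumpectomy",
                                 "mastectomy_fraction")) ||
    any(grepl("^(or_|arm_mean_)", stats))
  per_seed <- vapply(seeds, function(s) {
    co <- generate_cohort(config, seed = s, bank = bank, goals = goals)
    rec <- co$records
    out <- stats::setNames(numeric(length(stats)), stats)
    sc <- NULL
    score_of <- function(group) {
      if (is.null(sc)) sc <<- score_records(rec, bank, "reduced")
      sc[rec$group == group & rec$wave == "test"]
    }
    for (st in stats) {
      out[st] <- switch(
        st,
        patient_mean_knowledge = mean(score_of("patient"), na.rm = TRUE),
        provider_mean_knowledge = mean(score_of("provider"), na.rm = TRUE),
        control_mean_knowledge = mean(score_of("control"), na.rm = TRUE),
        patient_sd_knowledge = stats::sd(score_of("patient"), na.rm = TRUE),
        knowledge_gap = mean(score_of("provider"), na.rm = TRUE) -
          mean(score_of("patient"), na.rm = TRUE),
        screener_full_cor = {
          pat <- rec[rec$group == "patient" & rec$wave == "test", ]
          stats::cor(score_records(pat, bank, "screener"),
                     score_records(pat, bank, "reduced"),
                     use = "complete.obs")
        },
        cor_keep_remove = {
          pat <- patients_test(co)
          stats::cor(pat$g_keep_breast, pat$g_remove_breast,
                     use = "complete.obs")
        },
        patient_correct_k04 = {
          tok <- patients_test(co)$k04
          mean(tok[!is.na(tok)] == "3")
        },
        NA_real_)
    }
    if (need_model && anyNA(out[stats])) {
      ana <- apply_exclusions(co)
      em <- em_impute_goals(goal_matrix(ana, goals))
      fit <- fit_treatment_model(ana, em$completed)
      conc <- classify_concordance(fit)
      model_vals <- c(
        c_statistic = fit$c_statistic,
        concordance_overall = conc$overall_pct,
        concordance_mastectomy = conc$by_arm[["mastectomy"]],
        concordance_lumpectomy = conc$by_arm[["lumpectomy"]],
        mastectomy_fraction = mean(ana$treatment == "mastectomy"))
      for (st in names(model_vals))
        if (st %in% stats) out[st] <- model_vals[[st]]
      for (st in grep("^or_", stats, value = TRUE)) {
        term <- sub("^or_", "", st)
        out[st] <- fit$coefficients$or[fit$coefficients$term == term]
      }
      for (st in grep("^arm_mean_", stats, value = TRUE)) {
        bits <- sub("^arm_mean_", "", st)
        arm <- sub("^.*_(mastectomy|lumpectomy)$", "\\1", bits)
        g <- sub(paste0("_", arm, "$"), "", bits)
        out[st] <- mean(em$completed[ana$treatment == arm, g])
      }
    }
    if (need_retest && anyNA(out[stats])) {
      rt <- generate_retest(co, config, seed = s + 7919L)
      rep <- retest_report(co, rt)
      for (st in grep("_icc$", stats, value = TRUE)) {
        m <- sub("_icc$", "", st)
        m <- switch(m, knowledge = "knowledge_full", screener = "knowledge_screener", m)
        out[st] <- rep$icc[rep$measure == m]
      }
    }
    out
  }, numeric(length(stats)))
  if (length(stats) == 1L) per_seed <- matrix(per_seed, nrow = 1)
  stats::setNames(rowMeans(per_seed), stats)
}

#' Calibrate the generator against target statistics
#'
#' @param config starting `dqi_generator_config`.
#' @param targets data.frame with columns `name` (statistic), `value`,
#'   `tol`, `param` (config path) and optionally `step` (initial probe size,
#'   default 0.1).
#' @param n_seeds Monte-Carlo seeds per estimate (at least 20 for production
#'   use; fewer makes exploratory calibration cheaper but noisier).
#' @param max_iter coordinate-update iteration cap.
#' @param seed base seed for the Monte-Carlo blocks.
#' @param verbose print per-iteration progress.
#' @return calibrated config with attribute `"calibration_log"` (data.frame
#'   of iterates); errors listing the worst offender when some target cannot
#'   be reached.
#' @export
calibrate_generator <- function(config, targets, n_seeds = 20L, max_iter = 25L,
                                seed = 760613L, verbose = FALSE) {
  stopifnot(all(c("name", "value", "tol", "param") %in% names(targets)))
  if (is.null(targets$step)) targets$step <- 0.1
  seeds <- child_seeds(seed, n_seeds)
  prev_par <- prev_est <- rep(NA_real_, nrow(targets))
  log <- list()
  for (iter in seq_len(max_iter)) {
    est <- generator_statistics(config, targets$name, seeds)
    resid <- est - targets$value
    log[[iter]] <- data.frame(iter = iter, name = targets$name,
                              estimate = unname(est), target = targets$value,
                              stringsAsFactors = FALSE)
    if (verbose)
      message("iter ", iter, ": ",
              paste(sprintf("%s=%.3f", targets$name, est), collapse = ", "))
    if (all(abs(resid) <= targets$tol)) {
      attr(config, "calibration_log") <- do.call(rbind, log)
      return(config)
    }
    for (i in seq_len(nrow(targets))) {
      if (abs(resid[i]) <= targets$tol[i]) next
      par <- cfg_get(config, targets$param[i])
      if (is.na(prev_par[i]) || abs(par - prev_par[i]) < 1e-12 ||
          abs(est[i] - prev_est[i]) < 1e-12) {
        delta <- targets$step[i] * sign(targets$value[i] - est[i])
      } else {
        slope <- (est[i] - prev_est[i]) / (par - prev_par[i])
        delta <- if (abs(slope) < 1e-9) targets$step[i] *
          sign(targets$value[i] - est[i])
        else (targets$value[i] - est[i]) / slope
        delta <- sign(delta) * min(abs(delta), 5 * targets$step[i])
      }
      prev_par[i] <- par
      prev_est[i] <- est[i]
      config <- cfg_set(config, targets$param[i], par + delta)
    }
    cfg_check <- try(validate_generator_config(config), silent = TRUE)
    if (inherits(cfg_check, "try-error"))
      stop("calibration stepped outside the valid configuration space: ",
           attr(cfg_check, "condition")$message)
  }
  est <- generator_statistics(config, targets$name, seeds)
  resid <- abs(est - targets$value) / targets$tol
  worst <- which.max(resid)
  if (max(resid) > 1)
    stop("calibration failed after ", max_iter, " iterations; worst offender: ",
         targets$name[worst], " = ", signif(est[worst], 4), " (target ",
         targets$value[worst], " +/- ", targets$tol[worst], ")")
  attr(config, "calibration_log") <- do.call(rbind, log)
  config
}
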