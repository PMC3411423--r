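#' End-to-end decision-quality audit
#'
#' Runs the full pipeline on one cohort: knowledge scoring (reduced and
#' screener sets), item-retention diagnostics, the concordance model
#' (exclusions, EM imputation, logistic fit, classification, univariate
#' screen) and the psychometric battery (retest reliability when a retest
#' wave is available, content, discriminant, predictive validity,
#' preference gradient, feasibility), and bundles the results with a run
#' manifest (seed, package and generator versions, RNG, warnings, timings).
#'
#' @param cohort a `dqi_cohort`, or `NULL` to simulate one.
#' @param retest optional retest-wave `dqi_cohort`; simulated alongside the
#'   cohort when `cohort` is `NULL`.
#' @param config generator configuration used when simulating.
#' @param seed seed used when simulating (test wave; the retest wave derives
#'   its own seed from it).
#' @param out_dir optional directory; when given, the bundle is serialized
#'   as JSON (6 significant digits) plus CSV tables.
#' @return a `dqi_audit` list: `scores`, `screener_scores`, `diagnostics`,
#'   `concordance` (model, classification, univariate table, imputation),
#'   `psychometrics`, `manifest`.
#' @export
run_audit <- function(cohort = NULL, retest = NULL,
                      config = default_generator_config(), seed = 1L,
                      out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  warn <- character(0)
  note <- function(w) warn <<- c(warn, conditionMessage(w))

  if (is.null(cohort)) {
    cohort <- generate_cohort(config, seed = seed)
    retest <- generate_retest(cohort, config, seed = child_seeds(seed, 1L))
  }

  stage <- "knowledge scoring"
  result <- withCallingHandlers(
    tryCatch({
      scores <- score_cohort(cohort, "reduced")
      screener_scores <- score_cohort(cohort, "screener")
      stage <- "item diagnostics"
      diagnostics <- item_diagnostics(cohort)

      stage <- "concordance"
      analyzable <- apply_exclusions(cohort)
      em <- em_impute_goals(goal_matrix(analyzable, cohort$goals))
      model <- fit_treatment_model(analyzable, em$completed)
      concordance <- classify_concordance(model)
      univariate <- univariate_screen(analyzable, em$completed)

      stage <- "psychometrics"
      pat <- patients_test(cohort)
      screener_full_cor <- stats::cor(
        score_records(pat, cohort$item_bank, "screener"),
        score_records(pat, cohort$item_bank, "reduced"),
        use = "complete.obs")
      psychometrics <- list(
        reliability = if (!is.null(retest)) retest_report(cohort, retest) else NULL,
        content = content_validity(cohort),
        discriminant = discriminant_validity(scores, cohort),
        preference = preference_gradient(model, analyzable),
        predictive = predictive_validity(concordance, analyzable),
        feasibility = feasibility_report(cohort),
        screener_full_cor = screener_full_cor)

      list(scores = scores, screener_scores = screener_scores,
           diagnostics = diagnostics,
           concordance = list(model = model, classification = concordance,
                              univariate = univariate, imputation = em,
                              exclusions = attr(analyzable, "exclusions")),
           psychometrics = psychometrics)
    }, error = function(e)
      stop("audit failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })

  result$manifest <- list(
    package_version = as.character(utils::packageVersion("bcsdqi")),
    generator = cohort$provenance$generator %||% NA_character_,
    source = cohort$provenance$source,
    seed = cohort$provenance$seed %||% seed,
    rng = cohort$provenance$rng %||% paste(RNGkind(), collapse = "/"),
    warnings = warn,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(result) <- "dqi_audit"
  if (!is.null(out_dir)) write_audit(result, out_dir)
  result
}

#' @export
print.dqi_audit <- function(x, ...) {
  cat("Decision-quality audit (seed ", x$manifest$seed, ")\n\n", sep = "")
  print(x$scores)
  cat("\n")
  print(x$concordance$model)
  cat("\n")
  print(x$concordance$classification)
  rel <- x$psychometrics$reliability
  if (!is.null(rel)) {
    cat("\nRetest reliability (target ICC > 0.7):\n")
    rel$icc <- round_half_up(rel$icc, 2)
    print(rel, row.names = FALSE)
  }
  invisible(x)
}

# JSON-serializable view of an audit bundle (timestamps and fitted glm
# object excluded so identical seeds give byte-identical files)
audit_as_list <- function(audit) {
  m <- audit$concordance$model
  list(
    manifest = audit$manifest[setdiff(names(audit$manifest),
                                      c("timestamp", "elapsed_s"))],
    knowledge = list(summary = audit$scores$summary,
                     screener_summary = audit$screener_scores$summary,
                     hist_breaks = audit$scores$breaks,
                     hist = audit$scores$hist),
    diagnostics = list(items = audit$diagnostics$items,
                       recommended_set = audit$diagnostics$recommended_set),
    concordance = list(
      coefficients = m$coefficients,
      c_statistic = m$c_statistic,
      overall_pct = audit$concordance$classification$overall_pct,
      by_arm = as.list(audit$concordance$classification$by_arm),
      exclusions = as.list(audit$concordance$exclusions),
      univariate = audit$concordance$univariate,
      em_iterations = audit$concordance$imputation$n_iter),
    psychometrics = list(
      reliability = audit$psychometrics$reliability,
      provider_coverage = audit$psychometrics$content$provider_coverage,
      goal_top3 = audit$psychometrics$content$goal_top3,
      discriminant = list(
        anova_p = audit$psychometrics$discriminant$anova_p,
        contrasts = audit$psychometrics$discriminant$contrasts,
        goal_tests = audit$psychometrics$discriminant$goal_tests),
      preference = list(
        means = as.list(audit$psychometrics$preference$means),
        anova_p = audit$psychometrics$preference$anova_p),
      predictive = list(
        confidence = audit$psychometrics$predictive$confidence,
        regret = audit$psychometrics$predictive$regret),
      feasibility = list(
        knowledge_missing_mean = audit$psychometrics$feasibility$knowledge_missing_mean,
        goal_missing_median = audit$psychometrics$feasibility$goal_missing_median,
        offenders = audit$psychometrics$feasibility$offenders,
        completion = audit$psychometrics$feasibility$completion),
      screener_full_cor = audit$psychometrics$screener_full_cor))
}

#' Serialize an audit bundle
#'
#' Writes `audit.json` (all statistics, 6 significant digits) plus CSV
#' tables for the score summaries, item diagnostics and the treatment-model
#' table to `out_dir`.
#'
#' @param audit a `dqi_audit`.
#' @param out_dir output directory (created if absent).
#' @export
write_audit <- function(audit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(audit_as_list(audit),
                       file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE,
                       na = "null")
  utils::write.csv(audit$scores$summary,
                   file.path(out_dir, "knowledge_summary.csv"), row.names = FALSE)
  utils::write.csv(audit$diagnostics$items,
                   file.path(out_dir, "item_diagnostics.csv"), row.names = FALSE)
  utils::write.csv(audit$concordance$model$coefficients,
                   file.path(out_dir, "treatment_model.csv"), row.names = FALSE)
  utils::write.csv(audit$concordance$univariate,
                   file.path(out_dir, "univariate_screen.csv"), row.names = FALSE)
  invisible(out_dir)
}
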