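#' Cohort container and tabular I/O
#'
#' A cohort bundles one wide data.frame of respondent-wave records with the
#' item bank and goal bank its response columns refer to, plus provenance
#' (real vs synthetic, seed, generator version). Knowledge responses are
#' stored as character tokens: an option index (`"1"`, `"2"`, ...) or a
#' numeric value for open-ended parts, the distinct token `"not_sure"`, or
#' `NA` for missing -- "I am not sure" and missing are scored differently and
#' are never conflated.
#'
#' @name cohort
NULL

TREATMENTS <- c("mastectomy", "lumpectomy", "lumpectomy_then_mastectomy", "none")
STAGES <- c("I", "II", "none")
PREFERENCES <- c("mastectomy", "lumpectomy_radiation", "not_sure", "none")
REGRET_LEVELS <- c("definitely_yes", "probably_yes", "not_sure",
                   "probably_no", "definitely_no")
EDUCATION_LEVELS <- c("hs_or_less", "some_college", "college_plus")
GROUPS <- c("patient", "provider", "control")
WAVES <- c("test", "retest")

new_cohort <- function(records, item_bank, goals, provenance = NULL,
                       latents = NULL) {
  key <- paste(records$respondent_id, records$wave)
  if (anyDuplicated(key))
    stop("duplicate respondent_id within wave: ",
         paste(unique(records$respondent_id[duplicated(key)]), collapse = ", "))
  structure(list(records = records, item_bank = item_bank, goals = goals,
                 provenance = provenance %||% list(source = "real"),
                 latents = latents),
            class = "dqi_cohort")
}

#' @export
print.dqi_cohort <- function(x, ...) {
  r <- x$records
  cat("Decision-quality cohort (", x$provenance$source, ")\n", sep = "")
  tab <- table(r$group, r$wave)
  print(tab)
  invisible(x)
}

cohort_columns <- function(bank, goals) {
  list(core = c("respondent_id", "group", "wave", "treatment", "stage",
                "preference"),
       parts = bank_parts(bank)$part_id,
       goals = goal_cols(goals),
       extra = c("confidence", "regret", "top3_1", "top3_2", "top3_3",
                 "completion_minutes", "education", "coverage_rating",
                 "age", "race", "income", "marital"))
}

#' Read a cohort from a delimited text file
#'
#' Reads a CSV (or TSV, by file extension) with one row per respondent-wave.
#' Every cell is mapped to its typed value; cells that cannot be parsed or
#' fall outside their documented range (e.g. a goal rating of 11 on the 0-10
#' scale) are recorded as missing, and the total count of such cells is
#' attached as attribute `"parse_warnings"` and raised as a warning. Empty
#' cells and the literal token `"NA"` are missing; `"not_sure"` is a distinct
#' answered response.
#'
#' @param path file path.
#' @param bank item bank the knowledge columns refer to.
#' @param goals goal bank.
#' @return a `dqi_cohort`.
#' @export
read_cohort <- function(path, bank = default_item_bank(),
                        goals = default_goal_bank()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  cols <- cohort_columns(bank, goals)
  required <- c(cols$core, cols$parts, cols$goals)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing required columns: ",
         paste(missing_cols, collapse = ", "))

  n_bad <- 0L
  flag <- function(bad) n_bad <<- n_bad + sum(bad, na.rm = TRUE)

  rec <- raw
  if (anyNA(rec$respondent_id)) stop("respondent_id may not be missing")
  if (!all(rec$group %in% GROUPS))
    stop("invalid group values: ",
         paste(unique(rec$group[!rec$group %in% GROUPS]), collapse = ", "))
  if (!all(rec$wave %in% WAVES))
    stop("invalid wave values: ",
         paste(unique(rec$wave[!rec$wave %in% WAVES]), collapse = ", "))

  parse_factor <- function(x, levels) {
    bad <- !is.na(x) & !x %in% levels
    flag(bad); x[bad] <- NA_character_; x
  }
  parse_num <- function(x, lo = -Inf, hi = Inf, integer_only = FALSE) {
    v <- suppressWarnings(as.numeric(x))
    bad <- (!is.na(x) & is.na(v)) |
      (!is.na(v) & (v < lo | v > hi | (integer_only & v != round(v))))
    flag(bad); v[bad] <- NA_real_; v
  }

  rec$treatment <- parse_factor(rec$treatment, TREATMENTS)
  rec$stage <- parse_factor(rec$stage, STAGES)
  rec$preference <- parse_factor(rec$preference, PREFERENCES)

  pt <- bank_parts(bank)
  for (i in seq_len(nrow(pt))) {
    col <- pt$part_id[i]
    x <- rec[[col]]
    if (pt$kind[i] == "multiple_choice") {
      n_opt <- pt$k[i] - 1L
      idx <- suppressWarnings(as.integer(x))
      bad <- !is.na(x) & x != NOT_SURE &
        (is.na(idx) | idx < 1L | idx > n_opt)
      flag(bad)
      x[bad] <- NA_character_
    } else {
      v <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & x != NOT_SURE & is.na(v)
      flag(bad)
      x[bad] <- NA_character_
    }
    rec[[col]] <- x
  }
  for (col in cols$goals)
    rec[[col]] <- parse_num(rec[[col]], 0, 10, integer_only = TRUE)

  if ("confidence" %in% names(rec)) rec$confidence <- parse_num(rec$confidence, 0, 10)
  if ("regret" %in% names(rec)) rec$regret <- parse_factor(rec$regret, REGRET_LEVELS)
  if ("education" %in% names(rec)) rec$education <- parse_factor(rec$education, EDUCATION_LEVELS)
  if ("completion_minutes" %in% names(rec))
    rec$completion_minutes <- parse_num(rec$completion_minutes, lo = 1e-9)
  if ("coverage_rating" %in% names(rec))
    rec$coverage_rating <- parse_num(rec$coverage_rating, 1, 4, integer_only = TRUE)
  if ("age" %in% names(rec)) rec$age <- parse_num(rec$age, 0, 120)
  for (col in intersect(c("top3_1", "top3_2", "top3_3"), names(rec)))
    rec[[col]] <- parse_factor(rec[[col]], goals$goal_id)

  if (n_bad > 0L)
    warning(n_bad, " unparseable or out-of-range cells recorded as missing")
  out <- new_cohort(rec, bank, goals, provenance = list(source = "real", path = path))
  attr(out, "parse_warnings") <- n_bad
  out
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()]: typed values round-trip exactly for valid
#' files (missing cells are written empty).
#'
#' @param cohort a `dqi_cohort`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Data-completeness report for a cohort
#'
#' Reporting-only pass: per-field missingness percentages (knowledge parts
#' and goals among the groups that are asked them), the count of cells that
#' failed parsing on read, and retest records with no matching test record.
#'
#' @param cohort a `dqi_cohort`.
#' @return a `dqi_validation` list with `field_missing` (data.frame),
#'   `parse_warnings`, and `orphan_retest` (respondent ids).
#' @export
validate_cohort <- function(cohort) {
  r <- cohort$records
  cols <- cohort_columns(cohort$item_bank, cohort$goals)
  test <- r[r$wave == "test", , drop = FALSE]
  pat <- test[test$group == "patient", , drop = FALSE]
  miss_pct <- function(df, col)
    if (nrow(df) == 0L) NA_real_ else 100 * mean(is.na(df[[col]]))
  fields <- c(cols$parts, cols$goals, "confidence", "regret",
              "completion_minutes", "education")
  field_missing <- data.frame(
    field = fields,
    missing_pct = vapply(fields, function(col) {
      df <- if (col %in% cols$parts) test else pat
      miss_pct(df, col)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  retest <- r[r$wave == "retest", , drop = FALSE]
  orphan <- setdiff(retest$respondent_id, test$respondent_id)
  structure(list(field_missing = field_missing,
                 parse_warnings = attr(cohort, "parse_warnings") %||% 0L,
                 orphan_retest = orphan),
            class = "dqi_validation")
}

#' @export
print.dqi_validation <- function(x, ...) {
  cat("Cohort validation: ", x$parse_warnings, " parse warnings, ",
      length(x$orphan_retest), " orphan retest records\n", sep = "")
  worst <- x$field_missing[order(-x$field_missing$missing_pct), ][1:5, ]
  cat("Highest missingness:\n")
  print(worst, row.names = FALSE)
  invisible(x)
}

#' Demographic and treatment summary (printed-table style)
#'
#' Counts and percentages per categorical characteristic for one respondent
#' group, with percentages computed against the full group size and reported
#' to one decimal with half-up rounding, plus means/SDs for continuous ones.
#'
#' @param cohort a `dqi_cohort`.
#' @param group which respondent group to summarize (default patients).
#' @return a `dqi_cohort_summary`: list of data.frames keyed by
#'   characteristic, each with `level`, `n`, `pct`, plus `n_group` and a
#'   `continuous` table.
#' @export
summarize_cohort <- function(cohort, group = "patient") {
  r <- cohort$records
  df <- r[r$group == group & r$wave == "test", , drop = FALSE]
  n <- nrow(df)
  cat_vars <- intersect(c("race", "education", "income", "marital", "stage",
                          "treatment", "preference", "regret"), names(df))
  cats <- lapply(cat_vars, function(v) {
    tab <- table(df[[v]])
    if (length(tab) == 0L)
      return(data.frame(level = character(), n = integer(), pct = numeric()))
    data.frame(level = names(tab), n = as.integer(tab),
               pct = round_half_up(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  })
  names(cats) <- cat_vars
  cont_vars <- intersect(c("age", "completion_minutes", "confidence"), names(df))
  continuous <- data.frame(
    variable = cont_vars,
    mean = vapply(cont_vars, function(v) mean(df[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(cont_vars, function(v) stats::sd(df[[v]], na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(group = group, n_group = n, categorical = cats,
                 continuous = continuous),
            class = "dqi_cohort_summary")
}

#' @export
print.dqi_cohort_summary <- function(x, ...) {
  cat("Summary of ", x$n_group, " ", x$group, " records\n", sep = "")
  for (v in names(x$categorical)) {
    cat(v, ":\n", sep = "")
    print(x$categorical[[v]], row.names = FALSE)
  }
  invisible(x)
}

# convenience accessor used throughout the analysis modules
patients_test <- function(cohort) {
  r <- cohort$records
  r[r$group == "patient" & r$wave == "test", , drop = FALSE]
}

#' Extract the numeric goal-rating matrix from patient records
#'
#' @param records patient records data.frame.
#' @param goals goal bank.
#' @param model_only restrict to goals with `in_concordance_model` (default).
#' @return numeric matrix (respondents x goals, `NA` for missing).
#' @export
goal_matrix <- function(records, goals, model_only = TRUE) {
  g <- if (model_only) goals[goals$in_concordance_model, , drop = FALSE] else goals
  m <- as.matrix(records[, goal_cols(g), drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- g$goal_id
  rownames(m) <- records$respondent_id
  m
}
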