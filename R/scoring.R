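#' Knowledge scoring
#'
#' Scoring rules: each item is worth one point; a correct response scores 1
#' and an incorrect one 0; "I am not sure" is an answered, incorrect
#' response; a missing response scores 1/k, where k counts the response
#' choices including "I am not sure" (the expected score of blind guessing).
#' Open-ended items are correct when the value falls inside the item's
#' pre-determined clinical range. Multi-part items are the weighted sum of
#' their parts (weights sum to one). A respondent's score is 100 times the
#' point total divided by the item-set size, and is only defined when at
#' least 50% of the items in the set were answered ("not sure" counts as
#' answered; missing does not).
#'
#' @name knowledge_scoring
NULL

score_part <- function(token, part, kind) {
  if (is.na(token)) return(1 / part$k)
  if (token == NOT_SURE) return(0)
  if (kind == "multiple_choice") {
    idx <- suppressWarnings(as.integer(token))
    if (is.na(idx) || idx < 1L || idx > length(part$options))
      stop("option index '", token, "' out of range for part '", part$part_id, "'")
    as.numeric(idx == part$correct)
  } else {
    val <- suppressWarnings(as.numeric(token))
    if (is.na(val)) stop("unparseable open-ended response '", token, "'")
    as.numeric(val >= part$correct[1] && val <= part$correct[2])
  }
}

#' Score one item response
#'
#' @param response character token vector, one element per item part (option
#'   index or numeric value as character, `"not_sure"`, or `NA` for missing).
#' @param item a [knowledge_item()].
#' @return weight-adjusted item score in \[0, 1\].
#' @export
score_item <- function(response, item) {
  stopifnot(inherits(item, "dqi_item"))
  if (length(response) != length(item$parts))
    stop("item '", item$item_id, "' expects ", length(item$parts),
         " part responses, got ", length(response))
  sum(vapply(seq_along(item$parts), function(j)
    item$parts[[j]]$weight * score_part(response[j], item$parts[[j]], item$kind),
    numeric(1)))
}

# part tokens for one record row, as a named list per item
record_item_responses <- function(row, bank, ids) {
  lapply(bank[ids], function(it) {
    pids <- vapply(it$parts, `[[`, character(1), "part_id")
    as.character(unlist(row[pids], use.names = FALSE))
  })
}

#' Score one respondent over an item set
#'
#' @param record a single-row data.frame from a cohort (or a named list of
#'   part tokens).
#' @param bank item bank.
#' @param item_set `"reduced"` (default), `"screener"`, or `"initial"`.
#' @return score in \[0, 100\], or `NA` when fewer than 50% of the set's
#'   items were answered.
#' @export
score_respondent <- function(record, bank, item_set = "reduced") {
  ids <- item_set_ids(bank, item_set)
  resp <- record_item_responses(record, bank, ids)
  answered <- vapply(resp, function(tok) any(!is.na(tok)), logical(1))
  if (sum(answered) < 0.5 * length(ids)) return(NA_real_)
  pts <- vapply(ids, function(id) score_item(resp[[id]], bank[[id]]), numeric(1))
  100 * sum(pts) / length(ids)
}

# vectorized scoring over all rows of a records data.frame
score_records <- function(records, bank, item_set = "reduced") {
  ids <- item_set_ids(bank, item_set)
  n <- nrow(records)
  if (n == 0L) return(numeric(0))
  # per-part score matrix, then weighted item sums: much faster than rowwise
  pt <- bank_parts(bank)
  pt <- pt[pt$item_id %in% ids, , drop = FALSE]
  part_scores <- matrix(0, n, nrow(pt))
  part_answered <- matrix(FALSE, n, nrow(pt))
  for (j in seq_len(nrow(pt))) {
    it <- bank[[pt$item_id[j]]]
    part <- it$parts[[which(vapply(it$parts, `[[`, character(1), "part_id") == pt$part_id[j])]]
    tok <- as.character(records[[pt$part_id[j]]])
    sc <- numeric(n)
    miss <- is.na(tok)
    ns <- !miss & tok == NOT_SURE
    ok <- !miss & !ns
    sc[miss] <- 1 / part$k
    if (it$kind == "multiple_choice") {
      idx <- suppressWarnings(as.integer(tok[ok]))
      if (any(is.na(idx) | idx < 1L | idx > length(part$options)))
        stop("option index out of range in column '", pt$part_id[j], "'")
      sc[ok] <- as.numeric(idx == part$correct)
    } else {
      val <- suppressWarnings(as.numeric(tok[ok]))
      if (anyNA(val)) stop("unparseable open-ended response in column '", pt$part_id[j], "'")
      sc[ok] <- as.numeric(val >= part$correct[1] & val <= part$correct[2])
    }
    part_scores[, j] <- sc * part$weight
    part_answered[, j] <- !miss
  }
  item_of_part <- match(pt$item_id, ids)
  pts <- matrix(0, n, length(ids))
  answered <- matrix(FALSE, n, length(ids))
  for (j in seq_len(nrow(pt))) {
    pts[, item_of_part[j]] <- pts[, item_of_part[j]] + part_scores[, j]
    answered[, item_of_part[j]] <- answered[, item_of_part[j]] | part_answered[, j]
  }
  score <- 100 * rowSums(pts) / length(ids)
  score[rowSums(answered) < 0.5 * length(ids)] <- NA_real_
  score
}

#' Score a whole cohort
#'
#' @param cohort a `dqi_cohort`.
#' @param item_set item set to score (default the reduced set).
#' @param breaks histogram bin edges on the 0-100 scale.
#' @return a `dqi_scoreset`: per-respondent scores plus per-group/wave
#'   summaries (n, unscorable count, mean, SD) and histogram counts.
#' @export
score_cohort <- function(cohort, item_set = "reduced",
                         breaks = seq(0, 100, by = 10)) {
  r <- cohort$records
  scores <- data.frame(respondent_id = r$respondent_id, group = r$group,
                       wave = r$wave,
                       score = score_records(r, cohort$item_bank, item_set),
                       stringsAsFactors = FALSE)
  key <- interaction(scores$group, scores$wave, drop = TRUE)
  summ <- do.call(rbind, lapply(split(scores, key), function(s) {
    data.frame(group = s$group[1], wave = s$wave[1], n = nrow(s),
               n_unscorable = sum(is.na(s$score)),
               mean = mean(s$score, na.rm = TRUE),
               sd = stats::sd(s$score, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  hist_counts <- lapply(split(scores, key), function(s) {
    x <- s$score[!is.na(s$score)]
    as.integer(table(cut(x, breaks, include.lowest = TRUE, right = TRUE)))
  })
  structure(list(item_set = item_set, scores = scores, summary = summ,
                 breaks = breaks, hist = hist_counts),
            class = "dqi_scoreset")
}

#' @export
print.dqi_scoreset <- function(x, ...) {
  cat("Knowledge scores (", x$item_set, " item set)\n", sep = "")
  s <- x$summary
  s$mean <- round_half_up(s$mean, 1); s$sd <- round_half_up(s$sd, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

# per-item scored values (0/1 per part weight incl. 1/k for missing) for the
# patient group -- used by item-total and inter-item correlations
item_score_matrix <- function(records, bank, ids) {
  m <- vapply(ids, function(id) {
    resp <- records[, vapply(bank[[id]]$parts, `[[`, character(1), "part_id"),
                    drop = FALSE]
    apply(resp, 1, function(tok) score_item(as.character(tok), bank[[id]]))
  }, numeric(nrow(records)))
  colnames(m) <- ids
  m
}

#' Item retention diagnostics
#'
#' Applies the item-review heuristics: an item is flagged too easy when
#' healthy controls exceed 80% correct, too hard when providers average
#' below 50% correct, redundant when any inter-item correlation exceeds 0.8,
#' and problematic when more than 5% of responses are missing; a negative
#' corrected item-total correlation (item against the total excluding that
#' item, computed on patients) also flags the item. The returned
#' recommendation drops flagged items; final set membership remains a bank
#' configuration, as retention decisions are a review-panel judgement that
#' the flags inform rather than dictate.
#'
#' @param cohort a `dqi_cohort` containing all three respondent groups.
#' @param item_set which item set to diagnose (default the full initial set).
#' @return a `dqi_item_diagnostics` with per-item statistics, flags and the
#'   recommended reduced set.
#' @export
item_diagnostics <- function(cohort, item_set = "initial") {
  bank <- cohort$item_bank
  ids <- item_set_ids(bank, item_set)
  r <- cohort$records[cohort$records$wave == "test", , drop = FALSE]
  grp <- split(r, r$group)

  # observed percent correct among answered responses (missing excluded)
  pct_correct <- function(records, id) {
    if (is.null(records) || nrow(records) == 0L) return(NA_real_)
    it <- bank[[id]]
    vals <- vapply(it$parts, function(part) {
      tok <- as.character(records[[part$part_id]])
      tok <- tok[!is.na(tok)]
      if (length(tok) == 0L) return(NA_real_)
      mean(vapply(tok, score_part, numeric(1), part = part, kind = it$kind))
    }, numeric(1))
    100 * sum(vals * vapply(it$parts, `[[`, numeric(1), "weight"))
  }
  missing_pct <- function(records, id) {
    pids <- vapply(bank[[id]]$parts, `[[`, character(1), "part_id")
    100 * mean(is.na(as.matrix(records[, pids, drop = FALSE])))
  }

  pat <- grp[["patient"]]
  stats_df <- data.frame(
    item_id = ids,
    control_pct = vapply(ids, pct_correct, numeric(1), records = grp[["control"]]),
    provider_pct = vapply(ids, pct_correct, numeric(1), records = grp[["provider"]]),
    patient_pct = vapply(ids, pct_correct, numeric(1), records = pat),
    missing_pct = vapply(ids, missing_pct, numeric(1), records = r),
    row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(pat) && nrow(pat) > 2L) {
    m <- item_score_matrix(pat, bank, ids)
    tot <- rowSums(m)
    stats_df$item_total_r <- vapply(seq_along(ids), function(j)
      suppressWarnings(stats::cor(m[, j], tot - m[, j])), numeric(1))
    cm <- suppressWarnings(stats::cor(m))
    diag(cm) <- NA
    stats_df$max_inter_item_r <- apply(cm, 1, max, na.rm = TRUE)
  } else {
    stats_df$item_total_r <- NA_real_
    stats_df$max_inter_item_r <- NA_real_
  }

  stats_df$too_easy <- stats_df$control_pct > 80
  stats_df$too_hard <- stats_df$provider_pct < 50
  stats_df$negative_item_total <- stats_df$item_total_r < 0
  stats_df$redundant <- stats_df$max_inter_item_r > 0.8
  stats_df$excess_missing <- stats_df$missing_pct > 5
  flag_cols <- c("too_easy", "too_hard", "negative_item_total", "redundant",
                 "excess_missing")
  flagged <- rowSums(stats_df[flag_cols], na.rm = TRUE) > 0

  # score-level floor/ceiling check on the patient distribution
  floor_ceiling <- if (!is.null(pat) && nrow(pat) > 0L) {
    sc <- score_records(pat, bank, item_set)
    sc <- sc[!is.na(sc)]
    c(floor_pct = 100 * mean(sc <= 5), ceiling_pct = 100 * mean(sc >= 95))
  } else c(floor_pct = NA_real_, ceiling_pct = NA_real_)

  structure(list(items = stats_df,
                 recommended_set = ids[!flagged],
                 floor_ceiling = floor_ceiling),
            class = "dqi_item_diagnostics")
}

#' @export
print.dqi_item_diagnostics <- function(x, ...) {
  df <- x$items
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = 1)
  print(df, row.names = FALSE)
  cat("Recommended retained set:", paste(x$recommended_set, collapse = ", "), "\n")
  invisible(x)
}
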