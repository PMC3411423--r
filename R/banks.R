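#' Knowledge item banks and goal banks
#'
#' An item bank is an ordered list of knowledge-item definitions. Each item is
#' either multiple choice (an ordered set of substantive options plus an
#' implicit "I am not sure" choice) or open ended (a numeric answer judged
#' correct when it falls inside a pre-determined clinical range). Items may
#' have several parts; part weights sum to one so every item contributes one
#' point at most. The per-part count of response choices `k` (substantive
#' options plus "I am not sure") drives the 1/k score assigned to missing
#' responses.
#'
#' @name banks
NULL

NOT_SURE <- "not_sure"

#' Construct a knowledge item definition
#'
#' @param item_id identifier, used as (the stem of) the cohort column name.
#' @param kind `"multiple_choice"` or `"open_ended"`.
#' @param parts list of parts. Each part is a list with `part_id`, `weight`,
#'   and either `options` (character vector of substantive choices) plus
#'   `correct` (index into `options`) for multiple choice, or `correct = c(lo,
#'   hi)` plus `k` (response-choice count used for the 1/k missing rule) for
#'   open ended. Multiple-choice parts get `k = length(options) + 1`
#'   automatically ("I am not sure" counts as a choice).
#' @param in_screener,in_reduced_set membership flags for the 5-item screener
#'   and the reduced post-deletion item set.
#' @return a `dqi_item` list.
#' @export
knowledge_item <- function(item_id, kind = c("multiple_choice", "open_ended"),
                           parts, in_screener = FALSE, in_reduced_set = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  if (!is.list(parts) || length(parts) == 0L)
    stop("item '", item_id, "': at least one part is required")
  parts <- lapply(parts, function(p) {
    if (is.null(p$part_id)) stop("item '", item_id, "': every part needs a part_id")
    if (is.null(p$weight)) p$weight <- 1 / length(parts)
    if (kind == "multiple_choice") {
      if (is.null(p$options) || length(p$options) < 1L)
        stop("item '", item_id, "': multiple-choice parts need options")
      p$k <- length(p$options) + 1L
      if (p$k < 2L) stop("item '", item_id, "': k must be >= 2")
      if (length(p$correct) != 1L || is.na(p$correct) ||
          p$correct < 1L || p$correct > length(p$options))
        stop("item '", item_id, "': exactly one correct option index in range is required")
      p$correct <- as.integer(p$correct)
    } else {
      if (length(p$correct) != 2L || anyNA(p$correct) || p$correct[1] > p$correct[2])
        stop("item '", item_id, "': open-ended correct range must be c(lo, hi) with lo <= hi")
      if (is.null(p$k)) p$k <- 10L
      p$k <- as.integer(p$k)
      if (p$k < 1L) stop("item '", item_id, "': k must be positive")
    }
    p
  })
  w <- vapply(parts, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("item '", item_id, "': part weights must sum to 1 (got ", sum(w), ")")
  structure(list(item_id = item_id, kind = kind, parts = parts,
                 in_screener = isTRUE(in_screener),
                 in_reduced_set = isTRUE(in_reduced_set)),
            class = "dqi_item")
}

#' Assemble an item bank
#'
#' @param items list of [knowledge_item()] definitions.
#' @return a `dqi_item_bank` (validated ordered list).
#' @export
item_bank <- function(items) {
  stopifnot(is.list(items), length(items) > 0L)
  ok <- vapply(items, inherits, logical(1), "dqi_item")
  if (!all(ok)) stop("all elements must be knowledge_item() definitions")
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) stop("duplicate item_id in bank: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(items) <- ids
  structure(items, class = "dqi_item_bank")
}

#' @export
print.dqi_item_bank <- function(x, ...) {
  n_part <- sum(vapply(x, function(it) length(it$parts), integer(1)))
  cat("Knowledge item bank: ", length(x), " items (", n_part, " parts), ",
      sum(vapply(x, `[[`, logical(1), "in_reduced_set")), " in reduced set, ",
      sum(vapply(x, `[[`, logical(1), "in_screener")), " in screener\n", sep = "")
  invisible(x)
}

# flat part table: one row per part, used by scoring and the generator
bank_parts <- function(bank) {
  stopifnot(inherits(bank, "dqi_item_bank"))
  do.call(rbind, lapply(bank, function(it) {
    data.frame(item_id = it$item_id,
               part_id = vapply(it$parts, `[[`, character(1), "part_id"),
               kind = it$kind,
               k = vapply(it$parts, function(p) as.integer(p$k), integer(1)),
               weight = vapply(it$parts, `[[`, numeric(1), "weight"),
               stringsAsFactors = FALSE)
  }))
}

# item ids belonging to a named item set
item_set_ids <- function(bank, item_set = c("reduced", "screener", "initial")) {
  item_set <- match.arg(item_set)
  keep <- switch(item_set,
                 initial  = rep(TRUE, length(bank)),
                 reduced  = vapply(bank, `[[`, logical(1), "in_reduced_set"),
                 screener = vapply(bank, `[[`, logical(1), "in_screener"))
  ids <- names(bank)[keep]
  if (length(ids) == 0L) stop("item set '", item_set, "' is empty")
  ids
}

#' Goal bank
#'
#' Treatment goals and concerns rated on the 0 (not at all important) to 10
#' (extremely important) scale. `expected_direction` records which surgery a
#' high rating should push towards, and fixes the direction of the one-sided
#' discriminant-validity t-tests. The default bank carries the six canonical
#' goals plus two configurable placeholder slots (the fielded instrument has
#' eight goal items; only six are published).
#'
#' @param goals optional data.frame to validate instead of the default bank.
#' @return data.frame with columns `goal_id`, `label`, `expected_direction`
#'   (`"toward_mastectomy"` or `"toward_lumpectomy"`), `in_screener`,
#'   `in_concordance_model`.
#' @export
goal_bank <- function(goals = NULL) {
  if (is.null(goals)) goals <- default_goal_bank()
  need <- c("goal_id", "label", "expected_direction", "in_screener",
            "in_concordance_model")
  miss <- setdiff(need, names(goals))
  if (length(miss)) stop("goal bank missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(goals$goal_id)) stop("duplicate goal_id in goal bank")
  bad <- !goals$expected_direction %in% c("toward_mastectomy", "toward_lumpectomy")
  if (any(bad)) stop("invalid expected_direction for: ",
                     paste(goals$goal_id[bad], collapse = ", "))
  goals
}

#' @rdname goal_bank
#' @export
default_goal_bank <- function() {
  data.frame(
    goal_id = c("keep_breast", "remove_breast", "avoid_recurrence",
                "avoid_radiation", "radiation_side_effects", "radiation_hassle",
                "placeholder_1", "placeholder_2"),
    label = c("Keep your breast",
              "Remove the breast for peace of mind",
              "Avoid having cancer come back in the breast",
              "Avoid radiation",
              "Avoid serious side effects of radiation",
              "Avoid the hassle of radiation",
              "Placeholder goal 1", "Placeholder goal 2"),
    expected_direction = c("toward_lumpectomy", "toward_mastectomy",
                           "toward_mastectomy", "toward_mastectomy",
                           "toward_mastectomy", "toward_mastectomy",
                           "toward_mastectomy", "toward_mastectomy"),
    # screener keeps the three goals significant in the multivariable model
    # plus the recurrence concern (four goals)
    in_screener = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    in_concordance_model = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

goal_cols <- function(goals) paste0("g_", goals$goal_id)

#' Default knowledge item bank
#'
#' Fifteen items (13 multiple choice, 2 open ended): the five published items
#' (pre-treatment delay and survival, breast-cancer mortality with treatment,
#' re-excision likelihood, survival equivalence of the options, local
#' recurrence risk) with their printed option sets, plus ten synthetic items
#' standing in for the unpublished remainder of the fielded instrument. Items
#' k13/k14 are deliberately easy and k15 is keyed against the knowledge trait
#' in the synthetic generator, mirroring the three items the item-retention
#' review deleted; the reduced set is therefore k01-k12 and the screener is
#' the five published items.
#'
#' @return a `dqi_item_bank` of 15 items.
#' @export
default_item_bank <- function() {
  mc <- function(id, options, correct, screener = FALSE, reduced = TRUE)
    knowledge_item(id, "multiple_choice",
                   parts = list(list(part_id = id, options = options,
                                     correct = correct, weight = 1)),
                   in_screener = screener, in_reduced_set = reduced)
  generic4 <- c("Option A", "Option B", "Option C")
  items <- list(
    mc("k01", c("A lot", "Somewhat", "A little or not at all"), 3L, screener = TRUE),
    mc("k02", c("Most will die of breast cancer",
                "About half will die of breast cancer",
                "Most will die of something else"), 3L, screener = TRUE),
    mc("k03", c("Lumpectomy", "Mastectomy", "Equally likely for both"), 1L,
       screener = TRUE),
    mc("k04", c("Women who have a mastectomy",
                "Women who have a lumpectomy and radiation",
                "There is no difference"), 3L, screener = TRUE),
    mc("k05", c("Women who have a mastectomy",
                "Women who have a lumpectomy and radiation",
                "There is no difference"), 2L, screener = TRUE),
    knowledge_item("k06", "open_ended",
                   parts = list(list(part_id = "k06", correct = c(80, 90),
                                     k = 10L, weight = 1))),
    knowledge_item("k07", "open_ended",
                   parts = list(list(part_id = "k07", correct = c(50, 70),
                                     k = 10L, weight = 1))),
    mc("k08", generic4, 2L),
    mc("k09", generic4, 1L),
    mc("k10", generic4, 3L),
    mc("k11", generic4, 2L),
    knowledge_item("k12", "multiple_choice",
                   parts = list(list(part_id = "k12a", options = generic4,
                                     correct = 1L, weight = 0.5),
                                list(part_id = "k12b", options = generic4,
                                     correct = 3L, weight = 0.5))),
    mc("k13", generic4, 1L, reduced = FALSE),
    mc("k14", generic4, 2L, reduced = FALSE),
    mc("k15", generic4, 3L, reduced = FALSE)
  )
  item_bank(items)
}

#' Read or write bank definitions as YAML
#'
#' Round-trippable plain-text serialization so real instruments (whose item
#' wordings are not published) can be supplied as configuration.
#'
#' @param bank a `dqi_item_bank`; `goals` a goal bank data.frame.
#' @param path file path.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "dqi_item_bank"))
  out <- lapply(unclass(bank), function(it) {
    it$parts <- lapply(it$parts, function(p) { p$k <- as.integer(p$k); p })
    unclass(it)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  raw <- yaml::read_yaml(path)
  item_bank(lapply(raw, function(it)
    knowledge_item(it$item_id, it$kind,
                   parts = lapply(it$parts, function(p) {
                     if (it$kind == "open_ended") p$correct <- as.numeric(p$correct)
                     p
                   }),
                   in_screener = it$in_screener,
                   in_reduced_set = it$in_reduced_set)))
}

#' @rdname write_item_bank
#' @export
write_goal_bank <- function(goals, path) {
  yaml::write_yaml(lapply(seq_len(nrow(goals)), function(i) as.list(goals[i, ])), path)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_goal_bank <- function(path) {
  raw <- yaml::read_yaml(path)
  goal_bank(do.call(rbind, lapply(raw, function(g)
    data.frame(g[c("goal_id", "label", "expected_direction", "in_screener",
                   "in_concordance_model")], stringsAsFactors = FALSE))))
}
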