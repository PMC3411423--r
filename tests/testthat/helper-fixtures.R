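# Shared fixtures: all built in code at test time.

# small bank: two 4-choice items, one open-ended, one two-part item
tiny_bank <- function() {
  item_bank(list(
    knowledge_item("q1", "multiple_choice",
                   parts = list(list(part_id = "q1", options = c("a", "b", "c"),
                                     correct = 2L, weight = 1)),
                   in_screener = TRUE),
    knowledge_item("q2", "multiple_choice",
                   parts = list(list(part_id = "q2", options = c("a", "b", "c"),
                                     correct = 1L, weight = 1)),
                   in_screener = TRUE),
    knowledge_item("q3", "open_ended",
                   parts = list(list(part_id = "q3", correct = c(80, 90),
                                     k = 10L, weight = 1))),
    knowledge_item("q4", "multiple_choice",
                   parts = list(list(part_id = "q4a", options = c("a", "b", "c"),
                                     correct = 1L, weight = 0.5),
                                list(part_id = "q4b", options = c("a", "b", "c"),
                                     correct = 3L, weight = 0.5)))))
}

# records data.frame skeleton matching a bank/goal bank, n rows, all missing
blank_records <- function(n, bank = tiny_bank(), goals = default_goal_bank()) {
  df <- bcsdqi:::empty_records(n, bank, goals)
  df$respondent_id <- sprintf("R%03d", seq_len(n))
  df$group <- "patient"
  df
}

tiny_cohort <- function(records, bank = tiny_bank(), goals = default_goal_bank()) {
  bcsdqi:::new_cohort(records, bank, goals,
                      provenance = list(source = "synthetic", seed = 0L))
}

# a fast generator config for tests that only need structure, not calibration
small_config <- function(n_pat = 120L, n_prov = 40L, n_ctrl = 30L) {
  cfg <- default_generator_config()
  cfg$n_patients <- n_pat
  cfg$n_providers <- n_prov
  cfg$n_controls <- n_ctrl
  cfg$n_no_treatment <- min(6L, n_pat %/% 20L)
  cfg$retest_n <- min(60L, n_pat)
  cfg
}

# independent brute-force scorer: straight transcription of the scoring
# rules, one record and one item at a time
oracle_score <- function(row, bank, item_set) {
  ids <- bcsdqi:::item_set_ids(bank, item_set)
  n_answered <- 0
  total <- 0
  for (id in ids) {
    it <- bank[[id]]
    item_pts <- 0
    item_answered <- FALSE
    for (part in it$parts) {
      tok <- as.character(row[[part$part_id]])
      if (is.na(tok)) {
        item_pts <- item_pts + part$weight * (1 / part$k)
      } else {
        item_answered <- TRUE
        if (tok == "not_sure") {
          item_pts <- item_pts + 0
        } else if (it$kind == "multiple_choice") {
          item_pts <- item_pts + part$weight * (as.integer(tok) == part$correct)
        } else {
          v <- as.numeric(tok)
          item_pts <- item_pts +
            part$weight * (v >= part$correct[1] && v <= part$correct[2])
        }
      }
    }
    n_answered <- n_answered + item_answered
    total <- total + item_pts
  }
  if (n_answered < 0.5 * length(ids)) return(NA_real_)
  100 * total / length(ids)
}

# random valid response tokens for a bank
random_responses <- function(n, bank) {
  df <- blank_records(n, bank)
  for (row in seq_len(n)) {
    for (it in bank) {
      for (part in it$parts) {
        u <- runif(1)
        df[row, part$part_id] <-
          if (u < 0.15) NA_character_
          else if (u < 0.3) "not_sure"
          else if (it$kind == "multiple_choice")
            as.character(sample(length(part$options), 1))
          else as.character(round(runif(1, 0, 120)))
      }
    }
  }
  df
}

# brute-force c-statistic by explicit pair enumeration
oracle_cstat <- function(p, y) {
  y <- as.logical(y)
  wins <- 0
  for (i in which(y)) for (j in which(!y))
    wins <- wins + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  wins / (sum(y) * sum(!y))
}

# ICC oracle via the explicit two-way ANOVA decomposition, kept separate
# from the package implementation
oracle_icc <- function(x, y) {
  d <- cbind(x, y)
  n <- nrow(d); k <- 2
  grand <- mean(d)
  ssr <- k * sum((rowMeans(d) - grand)^2)
  ssc <- n * sum((colMeans(d) - grand)^2)
  sst <- sum((d - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
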