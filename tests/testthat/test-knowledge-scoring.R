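test_that("item scoring follows the stated rules", {
  bank <- tiny_bank()
  q1 <- bank$q1                       # 3 options + not sure -> k = 4
  expect_equal(score_item("2", q1), 1)
  expect_equal(score_item("1", q1), 0)
  expect_equal(score_item("not_sure", q1), 0)
  expect_equal(score_item(NA_character_, q1), 0.25)
  expect_error(score_item("9", q1), "out of range")

  q3 <- bank$q3                       # open-ended, range [80, 90], k = 10
  expect_equal(score_item("85", q3), 1)
  expect_equal(score_item("80", q3), 1)   # boundary inclusive
  expect_equal(score_item("91", q3), 0)
  expect_equal(score_item(NA_character_, q3), 0.1)

  q4 <- bank$q4                       # two parts, weights 0.5/0.5
  expect_equal(score_item(c("1", "3"), q4), 1)
  expect_equal(score_item(c("1", "1"), q4), 0.5)
  expect_equal(score_item(c(NA, "3"), q4), 0.5 * 0.25 + 0.5)
})

test_that("respondent scores apply the 50% completion rule", {
  bank <- default_item_bank()
  df <- blank_records(1, bank)
  # all 12 reduced-set items correct
  for (it in bank) for (part in it$parts)
    df[[part$part_id]] <- if (it$kind == "multiple_choice")
      as.character(part$correct) else as.character(mean(part$correct))
  expect_equal(score_respondent(df[1, ], bank, "reduced"), 100)

  # only 5 of 12 answered -> undefined
  df5 <- blank_records(1, bank)
  for (id in c("k01", "k02", "k03", "k04", "k05"))
    df5[[id]] <- as.character(bank[[id]]$parts[[1]]$correct)
  expect_true(is.na(score_respondent(df5[1, ], bank, "reduced")))
  # but it is scoreable as a screener (5 of 5 answered)
  expect_equal(score_respondent(df5[1, ], bank, "screener"), 100)

  # 11 correct + 1 missing (k = 4) of 12: 100 * 11.25 / 12
  df11 <- df
  df11$k01 <- NA_character_
  expect_equal(score_respondent(df11[1, ], bank, "reduced"), 93.75)

  expect_error(bcsdqi:::item_set_ids(item_bank(list(
    knowledge_item("x", "multiple_choice",
                   parts = list(list(part_id = "x", options = c("a", "b"),
                                     correct = 1L, weight = 1)),
                   in_screener = FALSE))), "screener"), "empty")
})

test_that("vectorized scoring agrees with the brute-force oracle", {
  set.seed(42)
  bank <- default_item_bank()
  df <- random_responses(1000, bank)
  for (set in c("reduced", "screener", "initial")) {
    fast <- bcsdqi:::score_records(df, bank, set)
    slow <- vapply(seq_len(nrow(df)), function(i)
      oracle_score(df[i, ], bank, set), numeric(1))
    expect_equal(fast, slow)
  }
})

test_that("scores are invariant to item and respondent order, and monotone", {
  set.seed(7)
  bank <- default_item_bank()
  df <- random_responses(50, bank)
  sc <- bcsdqi:::score_records(df, bank, "reduced")
  # respondent order
  perm <- sample(nrow(df))
  expect_equal(bcsdqi:::score_records(df[perm, ], bank, "reduced"), sc[perm])
  # item order (shuffle bank entries)
  bank2 <- item_bank(unclass(bank)[sample(length(bank))])
  expect_equal(bcsdqi:::score_records(df, bank2, "reduced"), sc)

  # monotonicity: flip one answered-incorrect response to correct
  ids <- bcsdqi:::item_set_ids(bank, "reduced")
  for (i in 1:20) {
    row <- df[i, , drop = FALSE]
    id <- sample(ids, 1)
    part <- bank[[id]]$parts[[1]]
    tok <- row[[part$part_id]]
    if (is.na(tok)) next
    row2 <- row
    row2[[part$part_id]] <- if (bank[[id]]$kind == "multiple_choice")
      as.character(part$correct) else as.character(mean(part$correct))
    expect_gte(bcsdqi:::score_records(row2, bank, "reduced"),
               bcsdqi:::score_records(row, bank, "reduced"))
    # answered-incorrect -> missing raises the score by exactly w/k / 12 * 100
    s1 <- bcsdqi:::score_records(row, bank, "reduced")
    row3 <- row
    row3[[part$part_id]] <- NA_character_
    s3 <- bcsdqi:::score_records(row3, bank, "reduced")
    pids <- vapply(bank[[id]]$parts, `[[`, character(1), "part_id")
    was_correct <- score_item(as.character(unlist(row[, pids])), bank[[id]]) >=
      score_item(as.character(unlist(row3[, pids])), bank[[id]])
    if (!is.na(s3) && !was_correct)
      expect_equal(s3 - s1, 100 * part$weight / part$k / length(ids))
  }
})

test_that("item diagnostics flag items at the stated thresholds", {
  bank <- tiny_bank()
  n <- 60
  mk <- function(group, p_correct) {
    df <- blank_records(n, bank)
    df$respondent_id <- paste0(substr(group, 1, 2), seq_len(n))
    df$group <- group
    for (it in bank) for (part in it$parts) {
      correct_tok <- if (it$kind == "multiple_choice")
        as.character(part$correct) else as.character(mean(part$correct))
      wrong_tok <- if (it$kind == "multiple_choice")
        as.character(setdiff(seq_along(part$options), part$correct)[1]) else "999"
      df[[part$part_id]] <- ifelse(runif(n) < p_correct, correct_tok, wrong_tok)
    }
    df
  }
  set.seed(1)
  df <- rbind(mk("patient", 0.5), mk("provider", 0.9), mk("control", 0.95))
  d <- item_diagnostics(tiny_cohort(df, bank))
  expect_true(all(d$items$too_easy))          # controls ~95% on every item
  expect_false(any(d$items$too_hard))

  # duplicated item responses -> redundant with correlation 1
  df2 <- df
  df2$q2 <- df2$q1
  bank2 <- item_bank(list(
    bank$q1,
    knowledge_item("q2", "multiple_choice",
                   parts = list(list(part_id = "q2", options = c("a", "b", "c"),
                                     correct = 2L, weight = 1)),
                   in_screener = TRUE),
    bank$q3, bank$q4))
  d2 <- item_diagnostics(tiny_cohort(df2, bank2))
  expect_true(all(d2$items$redundant[d2$items$item_id %in% c("q1", "q2")]))
  expect_equal(max(d2$items$max_inter_item_r), 1, tolerance = 1e-9)

  # provider average below 50% -> too hard
  set.seed(2)
  df3 <- rbind(mk("patient", 0.5), mk("provider", 0.3), mk("control", 0.5))
  d3 <- item_diagnostics(tiny_cohort(df3, bank))
  expect_true(all(d3$items$too_hard))
})

test_that("a reverse-keyed item shows a negative item-total correlation", {
  cfg <- small_config(400L, 40L, 30L)
  co <- generate_cohort(cfg, seed = 5)
  d <- item_diagnostics(co)
  it <- d$items
  expect_lt(it$item_total_r[it$item_id == "k15"], 0)
  expect_true(it$negative_item_total[it$item_id == "k15"])
  # the two deliberately easy items flag on the control threshold
  expect_true(all(it$too_easy[it$item_id %in% c("k13", "k14")]))
  # recommended set never keeps a flagged item
  expect_false(any(c("k13", "k14", "k15") %in% d$recommended_set))
})
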