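test_that("responses map to the printed welfare levels", {
  expect_equal(welfare_level("nut_water_work", "Limited access"), "medium")
  expect_equal(welfare_level("hlt_skin", "No signs present"), "good")
  expect_equal(welfare_level("nut_bcs", "Very thin/poor"), "bad")
  expect_true(is.na(welfare_level("hlt_skin", character(0))))
  expect_error(welfare_level("hlt_skin", "Bruises"),
               class = "wag_validation_error")
  expect_error(welfare_level("nope", "x"), class = "wag_schema_error")
})

test_that("multi-select levels are the worst of the selection", {
  expect_equal(welfare_level("hlt_skin", c("Scars", "Open wounds")), "bad")
  # exhaustive: every non-empty subset of the skin vocabulary
  lv <- wag_test_schema$levels[[match("hlt_skin", wag_test_schema$question_id)]]
  severity <- c(bad = 1, medium = 2, good = 3)
  n <- nrow(lv)
  for (mask in 1:(2^n - 1)) {
    sel <- lv$response[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    expected <- names(severity)[min(severity[lv$level[lv$response %in% sel]])]
    expect_equal(welfare_level("hlt_skin", sel), expected)
  }
})

test_that("adding a response never raises the welfare level", {
  lv <- wag_test_schema$levels[[match("beh_fear", wag_test_schema$question_id)]]
  severity <- c(bad = 1, medium = 2, good = 3)
  set.seed(42)
  for (i in 1:200) {
    base <- sample(lv$response, sample(nrow(lv) - 1, 1))
    extra <- sample(setdiff(lv$response, base), 1)
    expect_lte(
      severity[welfare_level("beh_fear", c(base, extra))],
      severity[welfare_level("beh_fear", base)]
    )
  }
})

test_that("alternative multi-select rules support sensitivity analysis", {
  rec <- make_good_records(1, hlt_skin = "Scars;Open wounds")
  lvl_of <- function(rule) {
    lv <- welfare_levels(rec, multiselect_rule = rule)
    lv$level[lv$question_id == "hlt_skin"]
  }
  expect_equal(lvl_of("worst"), "bad")     # Open wounds
  expect_equal(lvl_of("best"), "medium")   # Scars
  expect_equal(lvl_of("modal"), "bad")     # 1 medium vs 1 bad: tie -> worse

  rec2 <- make_good_records(1, hlt_skin = "Scars;Alopecia;Open wounds")
  lv2 <- welfare_levels(rec2, multiselect_rule = "modal")
  expect_equal(lv2$level[lv2$question_id == "hlt_skin"], "medium")

  # the switch propagates into category scores
  sc_worst <- score_records(rec)
  sc_best <- score_records(rec, multiselect_rule = "best")
  expect_lt(sc_worst$score[sc_worst$category == "health"],
            sc_best$score[sc_best$category == "health"])
})

test_that("level scores use the WAG point constants", {
  expect_equal(level_score("good"), 25)
  expect_equal(level_score("medium"), 12.5)
  expect_equal(level_score("bad"), 1)
  expect_error(score_config(good = 1, medium = 12.5, bad = 25),
               class = "wag_config_error")
})

test_that("category scores sum four question scores", {
  rec <- make_good_records(1)
  sc <- score_records(rec)
  expect_equal(nrow(sc), 5)
  expect_true(all(sc$score == 100))
  expect_true(all(sc$grade == "A"))

  # levels good, medium, medium, bad in nutrition -> 51 -> E
  rec2 <- make_good_records(
    1,
    nut_bcs = "Ideal",                    # good
    nut_diet = "Straights",               # medium
    nut_water_work = "Limited access",    # medium
    nut_fibre = "Rarely or never"         # bad
  )
  sc2 <- score_records(rec2)
  nut <- sc2[sc2$category == "nutrition", ]
  expect_equal(nut$score, 51)
  expect_equal(nut$grade, "E")

  # all bad -> 4 -> J
  rec3 <- make_good_records(
    1,
    hse_regime = "Kept outside - no access to shelter",
    hse_clean = "No", hse_dimensions = "Not-Satisfactory", hse_lying = "No"
  )
  hse <- score_records(rec3)
  hse <- hse[hse$category == "housing", ]
  expect_equal(hse$score, 4)
  expect_equal(hse$grade, "J")
})

test_that("alternate questions substitute for unanswered mains", {
  rec <- make_good_records(1, nut_fibre = NA_character_,
                           nut_water_housed = "Limited access")
  sc <- score_records(rec)
  nut <- sc[sc$category == "nutrition", ]
  expect_true(nut$complete)
  expect_equal(nut$score, 3 * 25 + 12.5)
  expect_equal(nut$alternates_used, "nut_fibre<-nut_water_housed")

  # answered main wins over the alternate
  rec2 <- make_good_records(1, nut_fibre = "Rarely or never",
                            nut_water_housed = "Free access")
  nut2 <- score_records(rec2)
  nut2 <- nut2[nut2$category == "nutrition", ]
  expect_equal(nut2$score, 3 * 25 + 1)
  expect_equal(nut2$alternates_used, "")

  # neither answered: category incomplete, no score, excluded downstream
  rec3 <- make_good_records(1, nut_fibre = NA_character_,
                            nut_water_housed = NA_character_)
  nut3 <- score_records(rec3)
  nut3 <- nut3[nut3$category == "nutrition", ]
  expect_false(nut3$complete)
  expect_true(is.na(nut3$score))
  expect_equal(nut3$n_answered, 3)
})

test_that("grades bin scores into half-open width-10 intervals", {
  expect_equal(grade_of_score(100), "A")
  expect_equal(grade_of_score(4), "J")
  expect_equal(grade_of_score(51), "E")
  expect_equal(grade_of_score(c(10, 10.5, 20, 90, 90.1)),
               c("J", "I", "I", "B", "A"))
  expect_error(grade_of_score(0), class = "wag_config_error")
  expect_error(grade_of_score(101), class = "wag_config_error")

  # attainable-sum closure: all sums of four values from {1, 12.5, 25} are
  # gradeable, and the bin lookup matches a linear interval scan
  scale <- grade_scale()
  for (s in attainable_scores()) {
    hits <- which(s > scale$lower & s <= scale$upper)
    expect_length(hits, 1)
    expect_equal(grade_of_score(s), scale$grade[hits])
  }
})

test_that("improving one question never lowers score or grade", {
  rec <- make_good_records(
    1,
    nut_bcs = "Very thin/poor", nut_diet = "Silage",
    nut_water_work = "No access", nut_fibre = "Rarely or never"
  )
  letters_worst_first <- c("J", "I", "H", "G", "F", "E", "D", "C", "B", "A")
  upgrades <- list(
    nut_bcs = c("Very thin/poor", "Fat", "Ideal"),
    nut_water_work = c("No access", "Limited access", "Free access")
  )
  for (q in names(upgrades)) {
    prev_score <- -Inf
    prev_rank <- 0
    for (resp in upgrades[[q]]) {
      r <- rec
      r[[q]] <- resp
      nut <- score_records(r)
      nut <- nut[nut$category == "nutrition", ]
      expect_gte(nut$score, prev_score)
      expect_gte(match(nut$grade, letters_worst_first), prev_rank)
      prev_score <- nut$score
      prev_rank <- match(nut$grade, letters_worst_first)
    }
  }
})
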