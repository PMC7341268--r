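test_that("population grading follows the worst-first 15% rule", {
  # single-bin population
  pg <- population_grade(data.frame(score = rep(100, 100)))
  expect_equal(pg$grade, "A")

  # exactly 15% in the worst bin grades J; 14% does not
  pg15 <- population_grade(data.frame(score = c(rep(5, 15), rep(95, 85))))
  expect_equal(pg15$grade, "J")
  pg14 <- population_grade(data.frame(score = c(rep(5, 14), rep(95, 86))))
  expect_equal(pg14$grade, "A")

  bins <- tidy(pg15)
  expect_equal(sum(bins$pct), 100, tolerance = 1e-9)
  expect_true(all(diff(bins$cum_pct) >= -1e-12))
  expect_equal(bins$cum_pct[10], 100, tolerance = 1e-9)
})

test_that("threshold comparison is exact at the 15% edge", {
  scores <- data.frame(score = c(rep(5, 15), rep(95, 85)))
  expect_equal(population_grade(scores, threshold_pct = 15)$grade, "J")
  expect_equal(population_grade(scores, threshold_pct = 14.999)$grade, "J")
  expect_equal(population_grade(scores, threshold_pct = 15.001)$grade, "A")
  # 3 of 20 = exactly 15%
  s20 <- data.frame(score = c(rep(4, 3), rep(100, 17)))
  expect_equal(population_grade(s20)$grade, "J")
  s20b <- data.frame(score = c(rep(4, 2), rep(100, 18)))
  expect_equal(population_grade(s20b)$grade, "A")
})

test_that("population grade matches the brute-force oracle", {
  set.seed(101)
  pool <- attainable_scores()
  for (i in 1:300) {
    n <- sample(1:400, 1)
    scores <- sample(pool, n, replace = TRUE)
    expect_equal(
      population_grade(data.frame(score = scores))$grade,
      oracle_population_grade(scores)
    )
  }
})

test_that("population grade is permutation-invariant and monotone", {
  set.seed(202)
  pool <- attainable_scores()
  letters_worst_first <- c("J", "I", "H", "G", "F", "E", "D", "C", "B", "A")
  for (i in 1:100) {
    scores <- sample(pool, 60, replace = TRUE)
    g1 <- population_grade(data.frame(score = scores))$grade
    g2 <- population_grade(data.frame(score = sample(scores)))$grade
    expect_equal(g1, g2)

    # raise one individual's score: grade never worsens
    j <- sample(60, 1)
    better <- scores
    higher <- pool[pool >= scores[j]]
    better[j] <- higher[sample.int(length(higher), 1)]
    g3 <- population_grade(data.frame(score = better))$grade
    expect_gte(match(g3, letters_worst_first), match(g1, letters_worst_first))
  }
})

test_that("incomplete scores are excluded and empty input errors", {
  df <- data.frame(score = c(5, NA, 95), complete = c(TRUE, FALSE, TRUE))
  pg <- population_grade(df)
  expect_equal(pg$n, 2)
  expect_equal(pg$n_excluded, 1)
  expect_error(population_grade(data.frame(score = NA_real_)),
               class = "wag_aggregation_error")
})

test_that("the grade matrix stratifies and excludes sparse strata", {
  pop <- generate_population(demo_config(n = 60, seed = 5))
  gm <- grade_matrix(pop)
  wide <- widen_grade_matrix(gm)
  expect_equal(
    names(wide),
    c("indicator", "stratum", "nutrition", "health", "behaviour",
      "housing", "working")
  )
  # single-district population: district row equals overall row
  expect_equal(
    unlist(wide[wide$stratum == "Dhading", -(1:2)]),
    unlist(wide[wide$stratum == "overall", -(1:2)])
  )
  # per-indicator stratum sizes sum to the population size
  for (ind in unique(gm$indicator)) {
    sub <- gm[gm$indicator == ind & gm$category == "nutrition", ]
    expect_equal(sum(sub$n), 60)
  }

  # three foals with min_stratum_n = 5 are excluded
  foals <- make_good_records(3, age_category = "foal")
  foals$equid_id <- paste0("F", 1:3)
  gm2 <- grade_matrix(dplyr::bind_rows(pop, foals))
  foal_rows <- gm2[gm2$stratum == "foal", ]
  expect_true(all(foal_rows$excluded))
  expect_true(all(is.na(foal_rows$grade)))
  expect_error(grade_matrix(pop, indicators = "height"),
               class = "wag_config_error")
})

test_that("response tables tally per-group and overall percentages", {
  rec <- make_good_records(4, nut_water_work = c(
    "Limited access", "Limited access", "No access", "No access"
  ))
  tab <- response_table(rec, "nut_water_work")
  expect_equal(tab$overall[tab$response == "Limited access"], 50)
  expect_equal(tab$overall[tab$response == "No access"], 50)
  expect_equal(tab$overall[tab$response == "Free access"], 0)

  # degenerate: one response everywhere
  rec2 <- make_good_records(5)
  tab2 <- response_table(rec2, "hlt_coat")
  expect_equal(tab2$overall[tab2$response == "Yes"], 100)

  # multi-select individuals count once per selected response
  rec3 <- make_good_records(4, hlt_skin = c(
    "Scars;Open wounds", "Scars", "No signs present", "No signs present"
  ))
  tab3 <- response_table(rec3, "hlt_skin")
  expect_equal(tab3$overall[tab3$response == "Scars"], 50)
  expect_equal(tab3$overall[tab3$response == "Open wounds"], 25)
  expect_equal(sum(tab3$overall), 125)
})

test_that("generated marginals land near their configuration", {
  cfg <- demo_config(n = 10000, seed = 9)
  pop <- generate_population(cfg)
  tab <- response_table(pop, "beh_attitude")
  # uniform over 4 responses: 25% each, 1.5 pp sampling tolerance
  expect_true(all(abs(tab$overall - 25) < 1.5))
  mc <- marginal_check(pop, cfg)
  expect_false(any(mc$flagged))
})

test_that("driver ranking matches a direct recount", {
  pop <- generate_population(demo_config(n = 200, seed = 12))
  for (cat in c("health", "housing")) {
    dr <- driver_report(pop, cat)
    expect_equal(nrow(dr), 4)
    expect_setequal(dr$rank, 1:4)
    lv <- welfare_levels(pop)
    recount <- lv[lv$question_id %in% dr$question_id, ] |>
      dplyr::group_by(question_id) |>
      dplyr::summarise(
        pct_bad = 100 * sum(level == "bad", na.rm = TRUE) / sum(!is.na(level))
      )
    m <- merge(dr, recount, by = "question_id")
    expect_equal(m$pct_bad.x, m$pct_bad.y)
    # returned in rank order: bad% non-increasing, medium% breaking ties
    expect_equal(dr$rank, 1:4)
    expect_true(all(diff(dr$pct_bad) <= 1e-9))
    ties <- which(abs(diff(dr$pct_bad)) <= 1e-9)
    expect_true(all(diff(dr$pct_medium)[ties] <= 1e-9))
  }

  # all-good population: zero proportions, stable input-order ranking
  good <- make_good_records(6)
  dr0 <- driver_report(good, "housing")
  expect_true(all(dr0$pct_bad == 0))
  expect_equal(dr0$question_id,
               c("hse_regime", "hse_clean", "hse_dimensions", "hse_lying"))

  # one question bad for everyone ranks first
  bad1 <- make_good_records(6, hse_clean = "No")
  expect_equal(driver_report(bad1, "housing")$question_id[1], "hse_clean")
})
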