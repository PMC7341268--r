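test_that("generation is deterministic under a fixed seed", {
  cfg <- demo_config(n = 50, seed = 6)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  c <- generate_population(cfg, seed = 7)
  expect_false(identical(a, c))
})

test_that("degenerate marginals produce constant responses", {
  cfg <- demo_config(n = 30, seed = 2)
  cfg$marginals <- cfg$marginals |>
    dplyr::mutate(prob = ifelse(
      question_id == "hlt_coat",
      ifelse(response == "Yes", 1, 0), prob
    ))
  pop <- generate_population(cfg)
  expect_true(all(pop$hlt_coat == "Yes"))
  mc <- marginal_check(pop, cfg)
  expect_equal(mc$max_abs_dev_pct[mc$question_id == "hlt_coat"], 0)
})

test_that("stratum counts are exact and streams are independent", {
  cfg <- demo_config(n = 80, seed = 10)
  pop <- generate_population(cfg)
  expect_equal(sum(pop$species == "horse"), 40)
  expect_equal(sum(pop$species == "mule"), 40)

  # growing stratum 1 leaves stratum 2's draws unchanged
  cfg2 <- cfg
  cfg2$strata$count[1] <- 60
  pop2 <- generate_population(cfg2)
  q <- wag_test_schema$question_id
  expect_identical(
    pop[pop$species == "mule", q],
    pop2[pop2$species == "mule", q]
  )
})

test_that("exclusive responses never co-occur with findings", {
  cfg <- demo_config(n = 400, seed = 13)
  # push skin marginals past 1 so two-response draws actually happen
  cfg$marginals <- cfg$marginals |>
    dplyr::mutate(prob = ifelse(question_id == "hlt_skin", 0.3, prob))
  pop <- generate_population(cfg)
  multi <- grep(";", pop$hlt_skin, fixed = TRUE, value = TRUE)
  expect_gt(length(multi), 0)
  expect_false(any(grepl("No signs present", multi, fixed = TRUE)))
  expect_equal(nrow(validate_records(pop)), 0)
})

test_that("invalid configurations are rejected with a field path", {
  cfg <- demo_config(n = 40, seed = 1)
  bad <- cfg
  bad$strata$count[1] <- -5
  expect_error(wagr:::.validate_synth_config(bad), "strata",
               class = "wag_config_error")
  bad2 <- cfg
  bad2$marginals$prob[1] <- -0.1
  expect_error(wagr:::.validate_synth_config(bad2), "marginals",
               class = "wag_config_error")
  # 100 equids cannot fill 1 kiln of at most 64
  expect_error(
    synth_config(
      strata = tibble::tibble(district = "Dhading", species = "horse",
                              sex = "gelding", age_category = "adult",
                              work_type = "pack", count = 100),
      kilns = tibble::tibble(district = "Dhading", n_kilns = 1L),
      handlers = tibble::tibble(district = "Dhading", n_handlers = 2L),
      marginals = demo_config(n = 8)$marginals
    ),
    class = "wag_config_error"
  )
})

test_that("the brick-kiln mimic reproduces the survey totals", {
  cfg <- brick_kiln_config(seed = 3)
  expect_equal(sum(cfg$strata$count), 2448)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 2448)
  expect_equal(sum(pop$species == "donkey"), 55)
  expect_equal(sum(pop$species == "mule"), 1028)
  expect_equal(sum(pop$species == "horse"), 1365)
  expect_equal(length(unique(pop$kiln_id)), 41)
  expect_equal(length(unique(pop$handler_id)), 126)
  expect_equal(sum(pop$district == "Dhading"), 1440)

  # kiln sizes within the plausible range
  sizes <- table(pop$kiln_id)
  expect_true(all(sizes >= 8 & sizes <= 64))

  # generator output validates with zero issues
  expect_equal(nrow(validate_records(pop)), 0)

  # the substituted mains stay unanswered; their alternates are answered
  expect_true(all(is.na(pop$nut_fibre)))
  expect_true(all(is.na(pop$wrk_age_started)))
  assessed <- pop$age_category != "foal"
  expect_true(all(!is.na(pop$nut_water_housed[assessed])))
  expect_true(all(is.na(pop$nut_bcs[!assessed])))

  # empirical marginals match the printed percentages
  mc <- marginal_check(pop, cfg)
  answered <- mc[!is.na(mc$max_abs_dev_pct), ]
  expect_false(any(answered$flagged))
})

test_that("a mismatched configuration is flagged", {
  cfg <- demo_config(n = 2000, seed = 15)
  pop <- generate_population(cfg)
  wrong <- cfg
  wrong$marginals <- wrong$marginals |>
    dplyr::mutate(prob = ifelse(
      question_id == "hlt_coat",
      ifelse(response == "Yes", 0.9, 0.1), prob
    ))
  mc <- marginal_check(pop, wrong)
  expect_true(mc$flagged[mc$question_id == "hlt_coat"])
})

test_that("marginal deviation shrinks with sample size", {
  devs <- vapply(c(250, 4000), function(n) {
    cfg <- demo_config(n = n, seed = 30)
    mc <- marginal_check(generate_population(cfg), cfg)
    mean(mc$max_abs_dev_pct, na.rm = TRUE)
  }, numeric(1))
  expect_lt(devs[2], devs[1])
})

test_that("a planted class effect shifts the hooked marginal", {
  cfg <- demo_config(n = 2000, seed = 18)
  cfg <- add_class_effect(cfg, "beh_handler", "Aggressive",
                          "hlt_lameness", "Severely lame", boost_pct = 30)
  pop <- generate_population(cfg)
  agg <- pop$beh_handler == "Aggressive"
  p_in <- mean(pop$hlt_lameness[agg] == "Severely lame")
  p_out <- mean(pop$hlt_lameness[!agg] == "Severely lame")
  expect_gt(p_in, p_out + 0.15)
})
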