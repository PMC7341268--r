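# Population-level aggregation of WAG category scores.

# Core rule on a numeric score vector: bin scores into grades, accumulate
# bin percentages from worst (J) to best (A), and return the first grade
# whose cumulative percentage reaches the threshold. The comparison is done
# on integer counts (cum_count * 100 >= threshold * n) so that e.g. exactly
# 15 of 100 individuals in the worst bin grades J without float-edge
# artifacts.
.pop_grade <- function(scores, threshold_pct, scale) {
  n <- length(scores)
  letter <- grade_of_score(scores, scale)
  counts <- table(factor(letter, levels = scale$grade))
  bins <- tibble(
    grade = scale$grade,
    count = as.integer(counts),
    pct = 100 * as.integer(counts) / n,
    cum_pct = cumsum(100 * as.integer(counts) / n)
  )
  cum_counts <- cumsum(as.integer(counts))
  hit <- which(cum_counts * 100 >= threshold_pct * n)
  list(grade = scale$grade[hit[1]], bins = bins, n = n)
}

#' Population WAG grade
#'
#' Aggregates individual category scores into one letter grade per category.
#' Scores are binned on the [grade_scale()]; bin percentages are accumulated
#' from the worst grade `J` to the best `A`, and the population grade is the
#' lowest (worst) grade at which the cumulative percentage of individuals
#' reaches `threshold_pct` (default 15%). Incomplete scores are excluded and
#' counted in `n_excluded`.
#'
#' @param scores A data frame with a numeric `score` column, e.g. from
#'   [score_records()]. If a `category` column is present, one grade is
#'   computed per category; if a `complete` column is present, incomplete
#'   rows are dropped first.
#' @param threshold_pct Cumulative percentage threshold (default 15).
#' @param scale A [grade_scale()].
#' @return A tibble of class `wag_population_grade` with one row per
#'   category: `category`, `n`, `n_excluded`, `threshold_pct`, `grade`, and
#'   a `bins` list-column holding the per-grade `count`, `pct` and `cum_pct`.
#' @examples
#' population_grade(data.frame(score = c(rep(4, 15), rep(100, 85))))
#' @export
population_grade <- function(scores, threshold_pct = 15,
                             scale = grade_scale()) {
  if (!is.data.frame(scores) || !"score" %in% names(scores)) {
    abort("`scores` must be a data frame with a `score` column",
          class = "wag_config_error")
  }
  category <- if ("category" %in% names(scores)) scores$category else
    rep("all", nrow(scores))
  complete <- if ("complete" %in% names(scores)) scores$complete else
    !is.na(scores$score)
  cats <- unique(category)
  cats <- cats[order(match(cats, c(.wag_categories, "all")), cats)]
  rows <- lapply(cats, function(cat) {
    in_cat <- category == cat
    kept <- scores$score[in_cat & complete & !is.na(scores$score)]
    if (length(kept) == 0) {
      abort(paste0("no complete scores to aggregate for category ", cat),
            class = "wag_aggregation_error")
    }
    res <- .pop_grade(kept, threshold_pct, scale)
    tibble(
      category = cat, n = res$n, n_excluded = sum(in_cat) - res$n,
      threshold_pct = threshold_pct, grade = res$grade, bins = list(res$bins)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("wag_population_grade", class(out))
  out
}

#' Stratified grade matrix
#'
#' Computes the population WAG grade of every welfare category within each
#' demographic stratum: overall, district, sex, species, age category and
#' work type. Strata with fewer than `min_stratum_n` complete scores in a
#' category are reported as excluded (no grade), mirroring the exclusion of
#' sparsely assessed groups such as foals.
#'
#' @inheritParams score_records
#' @param threshold_pct Cumulative percentage threshold (default 15).
#' @param min_stratum_n Minimum complete scores for a stratum grade
#'   (default 5).
#' @param indicators Demographic columns to stratify by.
#' @return A long tibble of class `wag_grade_matrix`: `indicator`, `stratum`,
#'   `category`, `n` (complete scores), `grade` (`NA` when excluded),
#'   `excluded`. Use [widen_grade_matrix()] for the one-row-per-stratum
#'   layout with five grade columns.
#' @export
grade_matrix <- function(records, schema = wag_schema(),
                         config = score_config(), scale = grade_scale(),
                         threshold_pct = 15, min_stratum_n = 5,
                         indicators = c("district", "sex", "species",
                                        "age_category", "work_type")) {
  bad_ind <- setdiff(indicators, names(records))
  if (length(bad_ind) > 0) {
    abort(paste0("unknown indicator(s): ", paste(bad_ind, collapse = ", ")),
          class = "wag_config_error")
  }
  scores <- score_records(records, schema, config, scale)
  demo <- records %>% select("equid_id", all_of(indicators))
  scored <- scores %>% left_join(demo, by = "equid_id")

  one_block <- function(df, indicator, stratum) {
    df %>%
      group_by(.data$category) %>%
      summarise(
        n = sum(.data$complete),
        grade = if (n >= min_stratum_n) {
          .pop_grade(.data$score[.data$complete], threshold_pct, scale)$grade
        } else {
          NA_character_
        },
        .groups = "drop"
      ) %>%
      mutate(indicator = indicator, stratum = stratum,
             excluded = .data$n < min_stratum_n)
  }

  blocks <- list(one_block(scored, "overall", "overall"))
  for (ind in indicators) {
    vals <- .demographic_vocab[[ind]] %||% sort(unique(scored[[ind]]))
    vals <- intersect(vals, unique(scored[[ind]]))
    for (v in vals) {
      blocks[[length(blocks) + 1]] <-
        one_block(scored[!is.na(scored[[ind]]) & scored[[ind]] == v, ], ind, v)
    }
  }

  out <- bind_rows(blocks) %>%
    mutate(category = factor(.data$category, levels = .wag_categories)) %>%
    arrange(match(.data$indicator, c("overall", indicators)),
            .data$stratum, .data$category) %>%
    mutate(category = as.character(.data$category)) %>%
    select("indicator", "stratum", "category", "n", "grade", "excluded")
  class(out) <- c("wag_grade_matrix", class(out))
  out
}

#' Widen a grade matrix to one row per stratum
#'
#' @param gm A [grade_matrix()] result.
#' @param excluded_label Cell text for excluded strata.
#' @return A tibble with `indicator`, `stratum` and one letter column per
#'   welfare category.
#' @export
widen_grade_matrix <- function(gm, excluded_label = "excluded") {
  gm %>%
    mutate(cell = if_else(.data$excluded, excluded_label, .data$grade)) %>%
    select("indicator", "stratum", "category", "cell") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "cell")
}

#' Response distribution table
#'
#' Tallies the responses to one question as percentages of answered
#' individuals, per group and overall — the layout of a published welfare
#' survey table. For multi-select questions an individual counts once per
#' selected response, so a column can exceed 100%.
#'
#' @inheritParams write_ears_csv
#' @param question A question id.
#' @param by Grouping demographic column (default `"species"`).
#' @return A tibble with `level`, `response`, one percentage column per
#'   group value, and `overall`. Percentages are unrounded.
#' @export
response_table <- function(records, question, schema = wag_schema(),
                           by = "species") {
  row <- schema[schema$question_id == question, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown question: ", question), class = "wag_schema_error")
  }
  if (!by %in% names(records)) {
    abort(paste0("unknown grouping column: ", by), class = "wag_config_error")
  }
  delim <- .schema_delimiter(schema)
  vocab <- row$levels[[1]]

  answered <- records[!is.na(records[[question]]), c("equid_id", by, question)]
  names(answered) <- c("equid_id", "group", "cell")
  long <- answered %>%
    tidyr::separate_longer_delim("cell", delim) %>%
    distinct(.data$equid_id, .data$group, response = .data$cell)

  tally_for <- function(df, label) {
    denom <- dplyr::n_distinct(df$equid_id)
    counts <- df %>% count(.data$response)
    tibble(response = vocab$response) %>%
      left_join(counts, by = "response") %>%
      mutate(!!label := 100 * dplyr::coalesce(.data$n, 0L) / max(denom, 1L)) %>%
      select(-"n")
  }

  groups <- sort(unique(answered$group))
  out <- tibble(level = vocab$level, response = vocab$response)
  for (g in groups) {
    out <- left_join(out, tally_for(long[long$group == g, ], g),
                     by = "response")
  }
  left_join(out, tally_for(long, "overall"), by = "response")
}

#' Poor-welfare drivers within a category
#'
#' Ranks the four question slots of a welfare category by the percentage of
#' individuals at the bad level (primary key) and then at the medium level
#' (secondary key), identifying which indicator contributes most to a poor
#' category grade. Each slot uses its main question's level, substituting
#' the alternate where the main is unanswered (as in scoring); the slot is
#' labelled by the question that actually supplied most answers.
#'
#' @inheritParams write_ears_csv
#' @param category One of `nutrition`, `health`, `behaviour`, `housing`,
#'   `working`.
#' @return A tibble of class `wag_driver_report`: `category`, `question_id`,
#'   `prompt`, `n`, `pct_bad`, `pct_medium`, `pct_good`, `rank`.
#' @export
driver_report <- function(records, category, schema = wag_schema()) {
  if (!category %in% .wag_categories) {
    abort(paste0("unknown category: ", category), class = "wag_config_error")
  }
  levels_long <- welfare_levels(records, schema)
  slots <- .schema_slots(schema) %>% filter(.data$category == !!category)

  main <- levels_long %>%
    filter(.data$question_id %in% slots$question_id) %>%
    select("equid_id", "question_id", main_level = "level")
  alt <- levels_long %>%
    filter(.data$question_id %in% slots$alternate_id) %>%
    select("equid_id", alternate_id = "question_id", alt_level = "level")

  resolved <- main %>%
    left_join(slots %>% select("question_id", "alternate_id"),
              by = "question_id") %>%
    left_join(alt, by = c("equid_id", "alternate_id")) %>%
    mutate(
      used_alt = is.na(.data$main_level) & !is.na(.data$alt_level),
      level = if_else(.data$used_alt, .data$alt_level, .data$main_level)
    )

  out <- resolved %>%
    group_by(.data$question_id, .data$alternate_id) %>%
    summarise(
      n = sum(!is.na(.data$level)),
      n_via_alternate = sum(.data$used_alt),
      pct_bad = 100 * sum(.data$level == "bad", na.rm = TRUE) / max(n, 1L),
      pct_medium = 100 * sum(.data$level == "medium", na.rm = TRUE) / max(n, 1L),
      pct_good = 100 * sum(.data$level == "good", na.rm = TRUE) / max(n, 1L),
      .groups = "drop"
    ) %>%
    mutate(
      label = if_else(!is.na(.data$alternate_id) &
                        .data$n_via_alternate > .data$n / 2,
                      .data$alternate_id, .data$question_id)
    ) %>%
    arrange(match(.data$question_id, slots$question_id))

  out <- out %>%
    mutate(order = rank(-(.data$pct_bad * 1e6 + .data$pct_medium),
                        ties.method = "first")) %>%
    left_join(schema %>% select(label = "question_id", "prompt"), by = "label") %>%
    mutate(category = category) %>%
    select("category", question_id = "label", "prompt", "n",
           "pct_bad", "pct_medium", "pct_good", rank = "order") %>%
    arrange(.data$rank)
  class(out) <- c("wag_driver_report", class(out))
  out
}
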