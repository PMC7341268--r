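#' Scoring configuration for WAG welfare levels
#'
#' Point values awarded per question by welfare level. The defaults are the
#' published WAG constants: good = 25, medium = 12.5, bad = 1, so a complete
#' four-question category scores between 4 (all bad) and 100 (all good).
#'
#' @param good,medium,bad Points per level; must satisfy
#'   `good > medium > bad > 0`.
#' @return A named list of class `wag_score_config`.
#' @export
score_config <- function(good = 25, medium = 12.5, bad = 1) {
  if (!(good > medium && medium > bad && bad > 0)) {
    abort("score_config requires good > medium > bad > 0",
          class = "wag_config_error")
  }
  structure(list(good = good, medium = medium, bad = bad),
            class = "wag_score_config")
}

#' The A-J grade scale
#'
#' Ten contiguous width-10 score bins from the worst grade `J` (scores of 1
#' to 10) to the best grade `A` (90 to 100). Interior bins are half-open
#' `(lower, upper]`, so a score of exactly 10 grades `J` and 100 grades `A`.
#'
#' @return A tibble with columns `grade`, `lower`, `upper`, ordered worst to
#'   best.
#' @export
grade_scale <- function() {
  tibble(
    grade = .wag_letters,
    lower = seq(0, 90, by = 10),
    upper = seq(10, 100, by = 10)
  )
}

#' Welfare level of a response set
#'
#' Maps the response(s) selected for one question to a welfare level. A
#' single-select question returns its mapped level; for a multi-select
#' question the worst level among the selected responses is returned
#' (`bad < medium < good`), so recording an additional finding can never
#' improve the level.
#'
#' @param question_id A question id present in `schema`.
#' @param responses Character vector of selected response strings.
#' @param schema A [wag_schema()].
#' @return `"good"`, `"medium"` or `"bad"`; `NA` if `responses` is empty
#'   (the question is unanswered).
#' @examples
#' welfare_level("nut_water_work", "Limited access")
#' welfare_level("hlt_skin", c("Scars", "Open wounds"))
#' @export
welfare_level <- function(question_id, responses, schema = wag_schema()) {
  row <- schema[schema$question_id == question_id, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown question: ", question_id), class = "wag_schema_error")
  }
  responses <- responses[!is.na(responses) & responses != ""]
  if (length(responses) == 0) return(NA_character_)
  lv <- row$levels[[1]]
  idx <- match(.match_key(responses), .match_key(lv$response))
  if (anyNA(idx)) {
    abort(
      paste0("response not in vocabulary of ", question_id, ": ",
             paste(responses[is.na(idx)], collapse = ", ")),
      class = "wag_validation_error"
    )
  }
  .worst_level(lv$level[idx])
}

#' Points for a welfare level
#'
#' @param level `"good"`, `"medium"` or `"bad"` (vectorised).
#' @param config A [score_config()].
#' @return Numeric points; `NA` for `NA` levels.
#' @export
level_score <- function(level, config = score_config()) {
  ok <- is.na(level) | level %in% .wag_levels
  if (!all(ok)) {
    abort("level must be one of good/medium/bad", class = "wag_config_error")
  }
  per <- c(good = config$good, medium = config$medium, bad = config$bad)
  unname(per[level])
}

#' Letter grade of a category score
#'
#' @param score Numeric score(s) in `(0, 100]`.
#' @param scale A [grade_scale()].
#' @return Grade letters `"A"`..`"J"`.
#' @examples
#' grade_of_score(c(100, 51, 4))
#' @export
grade_of_score <- function(score, scale = grade_scale()) {
  if (any(is.na(score)) || any(score <= 0 | score > max(scale$upper))) {
    abort("score must lie in (0, 100]", class = "wag_config_error")
  }
  idx <- findInterval(score, scale$upper, left.open = TRUE) + 1
  scale$grade[idx]
}

#' Per-question welfare levels for a record set
#'
#' Expands records to long form and assigns each answered question its
#' welfare level (worst-of for multi-select responses).
#'
#' @inheritParams write_ears_csv
#' @param multiselect_rule How to reduce a multi-response selection to one
#'   level: `"worst"` (default, conservative), `"best"`, or `"modal"` (most
#'   frequent level, ties resolved to the worse level). Intended for
#'   sensitivity analysis of multi-select questions such as the feed list.
#' @return A tibble with one row per (equid, question): `equid_id`,
#'   `question_id`, `category`, `role`, `level` (`NA` when unanswered).
#' @export
welfare_levels <- function(records, schema = wag_schema(),
                           multiselect_rule = c("worst", "best", "modal")) {
  multiselect_rule <- match.arg(multiselect_rule)
  delim <- .schema_delimiter(schema)
  long <- records %>%
    select("equid_id", all_of(schema$question_id)) %>%
    tidyr::pivot_longer(-"equid_id",
                        names_to = "question_id", values_to = "cell")
  lv <- .schema_levels(schema)
  expanded <- long %>%
    mutate(.row = row_number()) %>%
    tidyr::separate_longer_delim("cell", delim) %>%
    mutate(key = .match_key(.data$cell)) %>%
    left_join(lv %>% select("question_id", "key", "level"),
              by = c("question_id", "key"))
  unknown <- expanded %>% filter(!is.na(.data$cell), is.na(.data$level))
  if (nrow(unknown) > 0) {
    abort(
      paste0("responses not in vocabulary: ",
             paste(unique(paste0(unknown$question_id, "='", unknown$cell, "'")),
                   collapse = ", ")),
      class = "wag_validation_error"
    )
  }
  # reduction to one level per record, vectorised: order responses within
  # each record by severity (bad < medium < good; reversed for best-of, by
  # within-record level frequency for modal) and keep the first
  expanded$lvl_int <- match(expanded$level, .wag_levels)
  key <- switch(
    multiselect_rule,
    worst = expanded$lvl_int,
    best = -expanded$lvl_int,
    modal = {
      freq <- stats::ave(expanded$lvl_int,
                         expanded$.row, expanded$lvl_int,
                         FUN = length)
      -1000 * freq + expanded$lvl_int
    }
  )
  ord <- order(expanded$.row, key, na.last = TRUE)
  firsts <- expanded[ord, ][!duplicated(expanded$.row[ord]), ]
  worst <- firsts %>%
    mutate(level = ifelse(is.na(.data$lvl_int), NA_character_,
                          .wag_levels[.data$lvl_int])) %>%
    select("equid_id", "question_id", "level")
  worst %>%
    left_join(schema %>% select("question_id", "category", "role"),
              by = "question_id") %>%
    arrange(match(.data$equid_id, records$equid_id),
            match(.data$question_id, schema$question_id))
}

#' WAG category scores per equid
#'
#' Sums the four main-question scores of each welfare category for every
#' equid. Where a main question is unanswered and the schema defines an
#' answered alternate, the alternate's level is substituted (and recorded in
#' `alternates_used`). If neither main nor alternate is answered the category
#' is incomplete: it receives no score or grade and is excluded from
#' population aggregation.
#'
#' @inheritParams write_ears_csv
#' @inheritParams welfare_levels
#' @param config A [score_config()].
#' @param scale A [grade_scale()].
#' @return A tibble with one row per (equid, category): `equid_id`,
#'   `category`, `score`, `grade`, `complete`, `n_answered` (0-4),
#'   `alternates_used` (`"main<-alternate"` pairs joined by `";"`, `""` if
#'   none).
#' @examples
#' schema <- wag_schema()
#' pop <- generate_population(demo_config(n = 20, seed = 1))
#' score_records(pop, schema)
#' @export
score_records <- function(records, schema = wag_schema(),
                          config = score_config(), scale = grade_scale(),
                          multiselect_rule = c("worst", "best", "modal")) {
  levels_long <- welfare_levels(records, schema, multiselect_rule)
  slots <- .schema_slots(schema)

  main <- levels_long %>%
    filter(.data$role == "main") %>%
    select("equid_id", "question_id", "category", main_level = "level")
  alt <- levels_long %>%
    filter(.data$role == "alternate") %>%
    select("equid_id", alternate_id = "question_id", alt_level = "level")

  resolved <- main %>%
    left_join(slots %>% select("question_id", "alternate_id"),
              by = "question_id") %>%
    left_join(alt, by = c("equid_id", "alternate_id")) %>%
    mutate(
      used_alternate = is.na(.data$main_level) & !is.na(.data$alt_level),
      level = if_else(.data$used_alternate, .data$alt_level, .data$main_level)
    )

  scores <- resolved %>%
    mutate(points = level_score(.data$level, config)) %>%
    group_by(.data$equid_id, .data$category) %>%
    summarise(
      n_answered = sum(!is.na(.data$level)),
      complete = n_answered == 4L,
      score = if (complete) sum(points) else NA_real_,
      alternates_used = paste(
        sprintf("%s<-%s", .data$question_id[.data$used_alternate],
                .data$alternate_id[.data$used_alternate]),
        collapse = ";"
      ),
      .groups = "drop"
    )
  scores$grade <- NA_character_
  scores$grade[scores$complete] <-
    grade_of_score(scores$score[scores$complete], scale)

  scores %>%
    arrange(match(.data$equid_id, records$equid_id),
            match(.data$category, .wag_categories)) %>%
    select("equid_id", "category", "score", "grade", "complete",
           "n_answered", "alternates_used")
}
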