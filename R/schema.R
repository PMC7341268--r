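#' Load a WAG question schema
#'
#' Reads a machine-readable schema describing the indicator questions of a
#' WAG assessment: question id, prompt, welfare category, role (main or
#' alternate), whether multiple responses may be selected, and the mapping
#' from each response string to a welfare level (`good`, `medium`, `bad`).
#' The default is the schema shipped with the package: the 20 WAG questions
#' (five categories of four main questions each) plus the two alternate
#' questions used when a main question cannot be answered in the field.
#'
#' Schema invariants are checked on load: every response appears exactly once
#' in a question's level map, every alternate references a main question of
#' the same category, and each category has exactly four main questions.
#'
#' @param path Path to a schema YAML file. `NULL` loads the shipped schema.
#' @return A tibble of class `wag_schema` with one row per question and a
#'   `levels` list-column of `(response, level)` tibbles. The multi-select
#'   cell delimiter is stored in the `delimiter` attribute.
#' @examples
#' schema <- wag_schema()
#' dplyr::count(schema, category, role)
#' @export
wag_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "wag_schema.yaml", package = "wagr")
  raw <- yaml::read_yaml(path)
  qs <- purrr::map(raw$questions, function(q) {
    levels <- tibble(
      response = names(q$levels),
      level = unlist(q$levels, use.names = FALSE)
    )
    tibble(
      question_id = q$id,
      prompt = q$prompt,
      category = q$category,
      role = q$role %||% "main",
      alternate_for = q$alternate_for %||% NA_character_,
      multiselect = isTRUE(q$multiselect),
      exclusive = q$exclusive %||% NA_character_,
      levels = list(levels)
    )
  })
  schema <- bind_rows(qs)
  attr(schema, "delimiter") <- raw$multiselect_delimiter %||% ";"
  class(schema) <- c("wag_schema", class(schema))
  .check_schema(schema)
  schema
}

.schema_delimiter <- function(schema) attr(schema, "delimiter") %||% ";"

.check_schema <- function(schema) {
  if (anyDuplicated(schema$question_id)) {
    abort("duplicate question ids in schema", class = "wag_schema_error")
  }
  bad_cat <- setdiff(unique(schema$category), .wag_categories)
  if (length(bad_cat) > 0) {
    abort(
      paste0("unknown category: ", paste(bad_cat, collapse = ", ")),
      class = "wag_schema_error"
    )
  }
  for (i in seq_len(nrow(schema))) {
    lv <- schema$levels[[i]]
    if (anyDuplicated(lv$response) || anyDuplicated(.match_key(lv$response))) {
      abort(
        paste0("question ", schema$question_id[i],
               ": responses must appear exactly once in the level map"),
        class = "wag_schema_error"
      )
    }
    if (!all(lv$level %in% .wag_levels)) {
      abort(
        paste0("question ", schema$question_id[i], ": invalid welfare level"),
        class = "wag_schema_error"
      )
    }
    excl <- schema$exclusive[i]
    if (!is.na(excl) && !excl %in% lv$response) {
      abort(
        paste0("question ", schema$question_id[i],
               ": exclusive response not in vocabulary"),
        class = "wag_schema_error"
      )
    }
  }
  alts <- schema[schema$role == "alternate", ]
  for (i in seq_len(nrow(alts))) {
    main <- schema[schema$question_id == alts$alternate_for[i] &
                     schema$role == "main", ]
    if (nrow(main) != 1 || main$category != alts$category[i]) {
      abort(
        paste0("alternate ", alts$question_id[i],
               " must reference a main question of the same category"),
        class = "wag_schema_error"
      )
    }
  }
  mains <- schema[schema$role == "main", ]
  n_main <- table(factor(mains$category, levels = .wag_categories))
  if (!all(n_main == 4)) {
    abort("each category must have exactly 4 main questions",
          class = "wag_schema_error")
  }
  invisible(schema)
}

# Long lookup table: question_id, response, level, key (canonical match key).
.schema_levels <- function(schema) {
  schema %>%
    select("question_id", "levels") %>%
    tidyr::unnest("levels") %>%
    mutate(key = .match_key(.data$response))
}

# Main questions with their (single) alternate, if any.
.schema_slots <- function(schema) {
  mains <- schema %>%
    filter(.data$role == "main") %>%
    select("question_id", "category")
  alts <- schema %>%
    filter(.data$role == "alternate") %>%
    select(alternate_id = "question_id", question_id = "alternate_for")
  left_join(mains, alts, by = "question_id")
}
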