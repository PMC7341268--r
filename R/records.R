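#' Read EARS assessment records from CSV
#'
#' Loads a CSV export of EARS-style welfare assessment records (one row per
#' equid), canonicalises responses against the question vocabularies, and
#' validates the result. Matching is case-insensitive and whitespace-trimmed;
#' multi-select cells are split on the schema delimiter (default `";"`) and
#' stored re-joined in vocabulary order. Empty cells are treated as missing
#' (unanswered), never as an empty-string response.
#'
#' @param path Path to a CSV file with a header row naming every expected
#'   column: `equid_id`, `kiln_id`, `district`, `species`, `sex`,
#'   `age_category`, `work_type`, `handler_id`, and one column per question
#'   in `schema`.
#' @param schema A [wag_schema()] describing the questions.
#' @return A validated tibble of records with canonical response strings.
#' @seealso [write_ears_csv()], [validate_records()]
#' @export
read_ears_csv <- function(path, schema = wag_schema()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wag_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  expected <- c(.demographic_cols, schema$question_id)
  missing_cols <- setdiff(expected, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "wag_schema_error"
    )
  }
  records <- .canonicalise_records(raw[expected], schema)
  issues <- validate_records(records, schema)
  if (nrow(issues) > 0) {
    msgs <- sprintf(
      "row %d [%s] %s: %s", issues$row, issues$field,
      ifelse(is.na(issues$value), "<missing>", issues$value), issues$issue
    )
    abort(
      c("invalid EARS records:", utils::head(msgs, 20),
        if (nrow(issues) > 20) paste0("... and ", nrow(issues) - 20, " more")),
      class = "wag_validation_error",
      issues = issues
    )
  }
  records
}

#' Write EARS assessment records to CSV
#'
#' Writes records in a deterministic column order (demographic fields first,
#' then questions in schema order), UTF-8 encoded, with multi-select cells
#' joined by the schema delimiter and missing responses as empty cells.
#' A written file reloads to an identical record set via [read_ears_csv()].
#'
#' @param records A record tibble as returned by [read_ears_csv()] or
#'   [generate_population()].
#' @param path Output file path.
#' @param schema A [wag_schema()].
#' @return `path`, invisibly.
#' @export
write_ears_csv <- function(records, path, schema = wag_schema()) {
  cols <- c(.demographic_cols, schema$question_id)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    abort(
      paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")),
      class = "wag_schema_error"
    )
  }
  readr::write_csv(records[cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate EARS assessment records
#'
#' Checks records against the schema and controlled demographic vocabularies.
#' Issues are returned as data, one row per problem; an empty result means
#' the record set satisfies every invariant: unique equid ids, demographic
#' values from their closed vocabularies, responses from each question's
#' vocabulary, single-select questions carrying at most one response, and
#' exclusive multi-select responses not combined with others.
#'
#' @inheritParams write_ears_csv
#' @return A tibble with columns `row`, `equid_id`, `field`, `value`, `issue`.
#' @export
validate_records <- function(records, schema = wag_schema()) {
  delim <- .schema_delimiter(schema)
  issues <- list()
  add <- function(rows, field, values, issue) {
    if (length(rows) == 0) return()
    issues[[length(issues) + 1]] <<- tibble(
      row = as.integer(rows),
      equid_id = records$equid_id[rows],
      field = field,
      value = as.character(values),
      issue = issue
    )
  }

  miss_id <- which(is.na(records$equid_id) | records$equid_id == "")
  add(miss_id, "equid_id", NA, "missing equid id")
  dup <- which(duplicated(records$equid_id) & !is.na(records$equid_id))
  add(dup, "equid_id", records$equid_id[dup], "duplicate equid id")

  for (field in names(.demographic_vocab)) {
    vocab <- .demographic_vocab[[field]]
    vals <- records[[field]]
    bad <- which(!is.na(vals) & !(.match_key(vals) %in% .match_key(vocab)))
    add(bad, field, vals[bad], "value not in vocabulary")
  }

  lv <- .schema_levels(schema)
  for (i in seq_len(nrow(schema))) {
    qid <- schema$question_id[i]
    if (!qid %in% names(records)) next
    vocab_keys <- .match_key(schema$levels[[i]]$response)
    cells <- records[[qid]]
    answered <- which(!is.na(cells) & cells != "")
    if (length(answered) == 0) next
    parts <- strsplit(cells[answered], delim, fixed = TRUE)
    parts <- lapply(parts, trimws)
    n_resp <- lengths(parts)
    unknown <- vapply(
      parts, function(p) paste(p[!(.match_key(p) %in% vocab_keys)], collapse = delim),
      character(1)
    )
    bad <- which(unknown != "")
    add(answered[bad], qid, unknown[bad], "response not in vocabulary")
    if (!schema$multiselect[i]) {
      multi <- which(n_resp > 1)
      add(answered[multi], qid, cells[answered][multi],
          "multiple responses to a single-select question")
    } else if (!is.na(schema$exclusive[i])) {
      excl_key <- .match_key(schema$exclusive[i])
      clash <- which(n_resp > 1 & vapply(
        parts, function(p) excl_key %in% .match_key(p), logical(1)
      ))
      add(answered[clash], qid, cells[answered][clash],
          "exclusive response combined with other responses")
    }
  }

  if (length(issues) == 0) {
    tibble(
      row = integer(), equid_id = character(), field = character(),
      value = character(), issue = character()
    )
  } else {
    arrange(bind_rows(issues), .data$row, .data$field)
  }
}

# Map raw cells onto canonical vocabulary strings; unknown responses are kept
# verbatim so validate_records() can name them.
.canonicalise_records <- function(records, schema) {
  delim <- .schema_delimiter(schema)
  for (field in names(.demographic_vocab)) {
    vocab <- .demographic_vocab[[field]]
    idx <- match(.match_key(records[[field]]), .match_key(vocab))
    records[[field]] <- ifelse(is.na(idx), records[[field]], vocab[idx])
    records[[field]][!is.na(records[[field]]) & records[[field]] == ""] <- NA
  }
  for (i in seq_len(nrow(schema))) {
    qid <- schema$question_id[i]
    vocab <- schema$levels[[i]]$response
    cells <- records[[qid]]
    cells[!is.na(cells) & trimws(cells) == ""] <- NA
    answered <- which(!is.na(cells))
    if (length(answered) > 0) {
      canon <- vapply(
        strsplit(cells[answered], delim, fixed = TRUE),
        function(p) {
          p <- trimws(p)
          idx <- match(.match_key(p), .match_key(vocab))
          p <- ifelse(is.na(idx), p, vocab[idx])
          # canonical order: vocabulary order, unknowns last, deduplicated
          ord <- order(match(p, vocab), p)
          paste(unique(p[ord]), collapse = delim)
        },
        character(1)
      )
      cells[answered] <- canon
    }
    records[[qid]] <- cells
  }
  as_tibble(records)
}
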