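# End-to-end pipeline: validate -> score -> aggregate -> describe -> report.

.md_table <- function(df) {
  df <- dplyr::mutate(df, across(dplyr::everything(), function(x) {
    x <- if (is.numeric(x)) formatC(x, digits = 1, format = "f") else as.character(x)
    ifelse(is.na(x) | x == "NA", "", x)
  }))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

.file_hash <- function(path) {
  rlang::hash(readChar(path, file.size(path), useBytes = TRUE))
}

#' Run the full welfare-grading pipeline
#'
#' Validates (or generates) a population, scores every equid, aggregates the
#' stratified grade matrix, ranks poor-welfare drivers per category,
#' describes the handler-attitude classes, and writes a report bundle:
#' `records.csv`, `scores.csv`, `grade_matrix.csv`,
#' `grade_matrix_wide.csv`, `drivers.csv`, `response_tables.csv`,
#' `class_description.csv`, `report.md` and `manifest.json` (seed, config
#' hash, versions, file hashes — no timestamps, so a rerun at the same seed
#' reproduces the bundle byte for byte).
#'
#' @param input A record tibble, a path to an EARS CSV file, or a
#'   [synth_config()] to generate from.
#' @param out_dir Output directory (created if needed). `NULL` skips
#'   writing and returns the computed objects only.
#' @inheritParams grade_matrix
#' @param class_question Class variable for [describe_class()] (default
#'   handler attitude).
#' @param alpha,bh Passed to [describe_class()].
#' @param seed Seed for generation when `input` is a config (defaults to
#'   the config's own seed).
#' @return Invisibly, a list with `records`, `scores`, `grade_matrix`,
#'   `grade_matrix_wide`, `drivers`, `response_tables`,
#'   `class_description`, `manifest` and `paths`.
#' @export
run_pipeline <- function(input, out_dir = NULL, schema = wag_schema(),
                         config = score_config(), scale = grade_scale(),
                         threshold_pct = 15, min_stratum_n = 5,
                         alpha = 0.05, bh = FALSE,
                         class_question = "beh_handler", seed = NULL) {
  if (inherits(input, "wag_synth_config")) {
    seed <- seed %||% input$seed
    records <- generate_population(input, seed = seed)
  } else if (is.character(input)) {
    records <- read_ears_csv(input, schema)
  } else if (is.data.frame(input)) {
    records <- input
  } else {
    abort("input must be a record data frame, a CSV path, or a synth config",
          class = "wag_config_error")
  }
  issues <- validate_records(records, schema)
  if (nrow(issues) > 0) {
    abort(
      paste0("validation failed with ", nrow(issues),
             " issue(s); no outputs written"),
      class = "wag_validation_error", issues = issues
    )
  }

  scores <- score_records(records, schema, config, scale)
  gm <- grade_matrix(records, schema, config, scale, threshold_pct,
                     min_stratum_n)
  gm_wide <- widen_grade_matrix(gm)
  drivers <- bind_rows(lapply(.wag_categories, function(cat) {
    driver_report(records, cat, schema)
  }))
  rtabs <- bind_rows(lapply(schema$question_id, function(q) {
    tab <- response_table(records, q, schema)
    dplyr::bind_cols(tibble(question_id = q), tab)
  }))
  cd <- describe_class(records, class_question, alpha = alpha, bh = bh,
                       schema = schema)

  manifest <- list(
    seed = if (is.null(seed)) NA else as.integer(seed),
    parameters = list(
      threshold_pct = threshold_pct, min_stratum_n = min_stratum_n,
      alpha = alpha, bh = bh, class_question = class_question,
      score_good = config$good, score_medium = config$medium,
      score_bad = config$bad
    ),
    n_records = nrow(records),
    package = "wagr",
    package_version = as.character(utils::packageVersion("wagr")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  manifest$config_hash <- rlang::hash(manifest$parameters)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(out_dir, f)
    write_ears_csv(records, out("records.csv"), schema)
    readr::write_csv(scores, out("scores.csv"), na = "", progress = FALSE)
    readr::write_csv(gm, out("grade_matrix.csv"), na = "", progress = FALSE)
    readr::write_csv(gm_wide, out("grade_matrix_wide.csv"), na = "",
                     progress = FALSE)
    readr::write_csv(drivers, out("drivers.csv"), na = "", progress = FALSE)
    readr::write_csv(rtabs, out("response_tables.csv"), na = "",
                     progress = FALSE)
    readr::write_csv(as_tibble(cd), out("class_description.csv"), na = "",
                     progress = FALSE)

    report <- c(
      "# WAG welfare report", "",
      paste0("Records assessed: ", nrow(records)), "",
      "## Grade matrix", "",
      .md_table(gm_wide), "",
      "## Poor-welfare drivers", "",
      .md_table(drivers %>% select("category", "question_id", "n",
                                   "pct_bad", "pct_medium", "rank")), "",
      "## Class description", "",
      render_class_description(cd)
    )
    writeLines(report, out("report.md"))

    files <- c("records.csv", "scores.csv", "grade_matrix.csv",
               "grade_matrix_wide.csv", "drivers.csv", "response_tables.csv",
               "class_description.csv", "report.md")
    manifest$files <- lapply(
      setNames(file.path(out_dir, files), files), .file_hash
    )
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    paths <- c(setNames(file.path(out_dir, files), files),
               manifest.json = out("manifest.json"))
  }

  invisible(list(
    records = records, scores = scores, grade_matrix = gm,
    grade_matrix_wide = gm_wide, drivers = drivers,
    response_tables = rtabs, class_description = cd,
    manifest = manifest, paths = paths
  ))
}
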