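# Categorical description of a class variable (e.g. handler attitude)
# against the other survey questions, by comparing the class-conditional
# response proportion with the global proportion.

#' Exact two-proportion enrichment test
#'
#' Tests whether a response is over- or under-represented inside a class of
#' records, given the 2x2 margins. Under the null that class membership is
#' independent of the response, the joint count follows the central
#' hypergeometric law with parameters `(n_total, n_response, n_class)`. The
#' p-value is the doubled smaller exact tail, capped at 1; the statistic is
#' the signed standard-normal quantile of the one-sided mid-p (half the
#' probability of the observed count is attributed to the tail), positive
#' when the class proportion exceeds the global proportion. Both are
#' computed on the log scale so extreme enrichments remain finite.
#'
#' @param n_total Records under analysis.
#' @param n_class Records in the class.
#' @param n_response Records with the response.
#' @param n_both Records in the class with the response.
#' @return A tibble with columns `statistic` and `p_value` (vectorised over
#'   the inputs).
#' @examples
#' two_prop_test(100, 50, 40, 20) # class proportion equals global: null
#' two_prop_test(20, 5, 8, 5)
#' @export
two_prop_test <- function(n_total, n_class, n_response, n_both) {
  len <- max(length(n_total), length(n_class), length(n_response),
             length(n_both))
  n_total <- rep_len(n_total, len); n_class <- rep_len(n_class, len)
  n_response <- rep_len(n_response, len); n_both <- rep_len(n_both, len)
  ok <- n_total >= 1 & n_class >= 0 & n_response >= 0 &
    n_class <= n_total & n_response <= n_total &
    n_both >= pmax(0, n_class + n_response - n_total) &
    n_both <= pmin(n_class, n_response)
  if (any(!ok)) {
    abort("inconsistent counts: need 0 <= n_both <= min(n_class, n_response) etc.",
          class = "wag_config_error")
  }
  # tails of X ~ Hypergeometric(n_total, n_response, n_class), observed point
  # included in both
  p_hi <- phyper(n_both - 1, n_response, n_total - n_response, n_class,
                 lower.tail = FALSE)
  p_lo <- phyper(n_both, n_response, n_total - n_response, n_class)
  p_value <- pmin(1, 2 * pmin(p_hi, p_lo))
  p_value <- pmax(p_value, .Machine$double.xmin)

  # mid-p tails on the log scale: P[X > x] + 0.5 P[X = x] (upper) and
  # P[X < x] + 0.5 P[X = x] (lower); the statistic is taken from whichever
  # tail is the smaller so both strong enrichment and strong depletion keep
  # full floating-point precision
  log_eq <- stats::dhyper(n_both, n_response, n_total - n_response, n_class,
                          log = TRUE)
  log_gt <- phyper(n_both, n_response, n_total - n_response, n_class,
                   lower.tail = FALSE, log.p = TRUE)
  log_lt <- phyper(n_both - 1, n_response, n_total - n_response, n_class,
                   log.p = TRUE)
  log_midp_hi <- .log_sum_exp(log_gt, log_eq - log(2))
  log_midp_lo <- .log_sum_exp(log_lt, log_eq - log(2))
  statistic <- ifelse(
    log_midp_hi <= log_midp_lo,
    -qnorm(log_midp_hi, log.p = TRUE),
    qnorm(log_midp_lo, log.p = TRUE)
  )
  tibble(statistic = statistic, p_value = p_value)
}

# log(exp(a) + exp(b)), element-wise, stable
.log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  small <- pmin(a, b)
  out <- m + log1p(exp(small - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Describe a class variable by enriched responses
#'
#' Profiles each value of a single-select class question (typically handler
#' attitude) by the responses whose class-conditional proportion differs
#' from the global proportion, using [two_prop_test()]. Records missing the
#' class question are excluded; for each target question, proportions are
#' computed over the records that answered it. Each response of a
#' multi-select question is tested as its own presence/absence indicator.
#'
#' @inheritParams write_ears_csv
#' @param class_question A single-select question id whose values define the
#'   classes.
#' @param target_questions Question ids to profile (default: all questions
#'   except the class question).
#' @param alpha Retain entries with `p_value <= alpha` (default 0.05).
#' @param bh If `TRUE`, apply Benjamini-Hochberg correction across all tests
#'   before filtering.
#' @return A tibble of class `wag_class_description`, sorted by descending
#'   `|statistic|` within class value: `class_value`, `question_id`,
#'   `response`, `n_total`, `n_class`, `n_response`, `n_both`, `class_pct`,
#'   `global_pct`, `statistic`, `p_value`. The total number of tests
#'   performed (before filtering) is kept in the `n_tests` attribute.
#' @export
describe_class <- function(records, class_question,
                           target_questions = NULL, alpha = 0.05,
                           bh = FALSE, schema = wag_schema()) {
  row <- schema[schema$question_id == class_question, ]
  if (nrow(row) != 1) {
    abort(paste0("class question absent from schema: ", class_question),
          class = "wag_schema_error")
  }
  if (row$multiselect) {
    abort("class question must be single-select", class = "wag_config_error")
  }
  target_questions <- target_questions %||%
    setdiff(schema$question_id, class_question)
  bad_targets <- setdiff(target_questions, schema$question_id)
  if (length(bad_targets) > 0) {
    abort(paste0("unknown target question(s): ",
                 paste(bad_targets, collapse = ", ")),
          class = "wag_schema_error")
  }
  delim <- .schema_delimiter(schema)

  cls <- records[[class_question]]
  keep <- !is.na(cls)
  records <- records[keep, ]
  cls <- cls[keep]
  class_values <- schema$levels[[match(class_question, schema$question_id)]]$response
  class_values <- intersect(class_values, unique(cls))

  entries <- list()
  for (qid in target_questions) {
    cells <- records[[qid]]
    answered <- !is.na(cells)
    if (!any(answered)) next
    n_total <- sum(answered)
    cls_q <- cls[answered]
    vocab <- schema$levels[[match(qid, schema$question_id)]]$response
    parts <- strsplit(cells[answered], delim, fixed = TRUE)
    # presence/absence indicator matrix: individuals x responses
    resp_long <- tibble(
      idx = rep(seq_along(parts), lengths(parts)),
      response = unlist(parts)
    ) %>% distinct()
    counts <- resp_long %>%
      mutate(class_value = cls_q[.data$idx]) %>%
      count(.data$response, .data$class_value, name = "n_both")
    totals <- resp_long %>% count(.data$response, name = "n_response")
    class_sizes <- tibble(class_value = cls_q) %>%
      count(.data$class_value, name = "n_class")
    grid <- tidyr::expand_grid(
      response = intersect(vocab, totals$response),
      class_value = class_values
    ) %>%
      left_join(totals, by = "response") %>%
      left_join(class_sizes, by = "class_value") %>%
      left_join(counts, by = c("response", "class_value")) %>%
      mutate(
        n_both = dplyr::coalesce(.data$n_both, 0L),
        n_class = dplyr::coalesce(.data$n_class, 0L),
        n_total = n_total,
        question_id = qid
      ) %>%
      filter(.data$n_class > 0)
    entries[[length(entries) + 1]] <- grid
  }
  if (length(entries) == 0) {
    abort("no answered target questions", class = "wag_aggregation_error")
  }
  all_entries <- bind_rows(entries)
  test <- two_prop_test(all_entries$n_total, all_entries$n_class,
                        all_entries$n_response, all_entries$n_both)
  all_entries <- all_entries %>%
    mutate(
      class_pct = 100 * .data$n_both / .data$n_class,
      global_pct = 100 * .data$n_response / .data$n_total,
      statistic = test$statistic,
      p_value = if (bh) stats::p.adjust(test$p_value, "BH") else test$p_value
    )
  n_tests <- nrow(all_entries)

  out <- all_entries %>%
    filter(.data$p_value <= alpha) %>%
    arrange(match(.data$class_value, class_values),
            desc(abs(.data$statistic)), desc(.data$statistic),
            .data$question_id, .data$response) %>%
    select("class_value", "question_id", "response", "n_total", "n_class",
           "n_response", "n_both", "class_pct", "global_pct", "statistic",
           "p_value")
  attr(out, "n_tests") <- n_tests
  attr(out, "alpha") <- alpha
  attr(out, "class_question") <- class_question
  class(out) <- c("wag_class_description", class(out))
  out
}

#' Render a class description as report text
#'
#' Formats [describe_class()] entries in the conventional narrative style:
#' `response (class% vs. global% global, p = ...)`, grouped by class value.
#'
#' @param cd A [describe_class()] result.
#' @param max_per_class Entries rendered per class value.
#' @return A character vector of report lines.
#' @export
render_class_description <- function(cd, max_per_class = 10) {
  fmt_p <- function(p) {
    if_else(p < 0.001, "p < 0.001", sprintf("p = %.3f", p))
  }
  lines <- character()
  for (cv in unique(cd$class_value)) {
    sub <- head(cd[cd$class_value == cv, ], max_per_class)
    items <- sprintf(
      "%s: %s (%.1f%% vs. %.1f%% global, %s)",
      sub$question_id, sub$response, sub$class_pct, sub$global_pct,
      fmt_p(sub$p_value)
    )
    lines <- c(lines, paste0("## ", cv), items, "")
  }
  lines
}
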