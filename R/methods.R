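# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.wag_population_grade <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select("category", "n", "threshold_pct", "bins") %>%
    tidyr::unnest("bins")
}

#' @export
glance.wag_population_grade <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select("category", "n", "n_excluded", "threshold_pct", "grade")
}

#' @export
tidy.wag_grade_matrix <- function(x, ...) as_tibble(x)

#' @export
tidy.wag_class_description <- function(x, ...) as_tibble(x)

#' @export
glance.wag_class_description <- function(x, ...) {
  tibble(
    class_question = attr(x, "class_question"),
    n_tests = attr(x, "n_tests"),
    n_retained = nrow(x),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.wag_driver_report <- function(x, ...) as_tibble(x)

#' Plot the grade-bin distribution behind a population grade
#'
#' Bars show the percentage of individuals per grade bin (worst `J` to best
#' `A`); the line shows the worst-first cumulative percentage and the dashed
#' rule the aggregation threshold.
#'
#' @param object A [population_grade()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wag_population_grade <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(grade = factor(.data$grade, levels = .wag_letters))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pct), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_pct, group = 1),
                       colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_pct), colour = "grey30") +
    ggplot2::geom_hline(yintercept = object$threshold_pct[1],
                        linetype = "dashed") +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "grade (worst to best)", y = "% of individuals")
}

#' Plot a stratified grade matrix as a tile map
#'
#' @param object A [grade_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wag_grade_matrix <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(
      stratum = factor(.data$stratum, levels = rev(unique(.data$stratum))),
      category = factor(.data$category, levels = .wag_categories),
      grade = factor(.data$grade, levels = .wag_letters)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$stratum,
                                   fill = .data$grade)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = if_else(.data$excluded, "excl.", .data$grade)
    ), size = 3) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = 1,
                               drop = FALSE, na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "grade")
}

#' Plot poor-welfare drivers within a category
#'
#' @param object A [driver_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wag_driver_report <- function(object, ...) {
  df <- as_tibble(object) %>%
    select("question_id", "pct_bad", "pct_medium") %>%
    tidyr::pivot_longer(-"question_id", names_to = "level",
                        values_to = "pct") %>%
    mutate(
      level = factor(.data$level, levels = c("pct_bad", "pct_medium"),
                     labels = c("bad", "medium")),
      question_id = factor(.data$question_id,
                           levels = rev(object$question_id))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$question_id,
                                   fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(bad = "firebrick",
                                          medium = "goldenrod")) +
    ggplot2::labs(x = "% of individuals", y = NULL, fill = "welfare level")
}

#' Plot class-description enrichments
#'
#' @param object A [describe_class()] result.
#' @param max_per_class Entries shown per class value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wag_class_description <- function(object, max_per_class = 8, ...) {
  df <- as_tibble(object) %>%
    group_by(.data$class_value) %>%
    slice(seq_len(min(n(), max_per_class))) %>%
    ungroup() %>%
    mutate(label = paste0(.data$question_id, ": ", .data$response))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   y = stats::reorder(.data$label,
                                                      abs(.data$statistic)))) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$statistic > 0)) +
    ggplot2::facet_wrap(~class_value, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "enrichment statistic (normal scale)", y = NULL)
}
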