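# Shared fixtures and independent oracles.

wag_test_schema <- wag_schema()

# A tiny hand-built record tibble: every demographic field valid, all
# questions unanswered unless set via `...` (question_id = value pairs are
# applied to all rows unless given as a vector).
make_records <- function(n = 3, ...) {
  rec <- tibble::tibble(
    equid_id = sprintf("T%03d", seq_len(n)),
    kiln_id = "DHA-K01",
    district = "Dhading",
    species = rep_len(c("horse", "mule", "donkey"), n),
    sex = "gelding",
    age_category = "adult",
    work_type = "pack",
    handler_id = "DHA-H001"
  )
  for (q in wag_test_schema$question_id) rec[[q]] <- NA_character_
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- rep_len(dots[[nm]], n)
  rec
}

# Fill every question with its first "good"-level response so records are
# complete and uniformly good; then override selected questions.
make_good_records <- function(n = 3, ...) {
  rec <- make_records(n)
  for (i in seq_len(nrow(wag_test_schema))) {
    lv <- wag_test_schema$levels[[i]]
    rec[[wag_test_schema$question_id[i]]] <-
      lv$response[match("good", lv$level)]
  }
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- rep_len(dots[[nm]], n)
  rec
}

# Independent brute-force population grading oracle: sort scores into bins
# by linear scan against the interval table, accumulate percentages worst
# to best, scan for the first bin meeting the threshold.
oracle_population_grade <- function(scores, threshold_pct = 15) {
  letters_worst_first <- c("J", "I", "H", "G", "F", "E", "D", "C", "B", "A")
  lower <- seq(0, 90, by = 10)
  upper <- seq(10, 100, by = 10)
  bin_of <- function(s) {
    for (b in seq_along(upper)) {
      if (s > lower[b] && s <= upper[b]) return(b)
    }
    stop("score out of range")
  }
  bins <- vapply(scores, bin_of, integer(1))
  cum <- 0
  for (b in seq_along(upper)) {
    cum <- cum + 100 * sum(bins == b) / length(scores)
    if (cum >= threshold_pct - 1e-12) return(letters_worst_first[b])
  }
  stop("threshold never reached")
}

# Exhaustive hypergeometric oracle: pmf over all feasible joint counts via
# binomial coefficients, doubled smaller tail capped at 1.
oracle_two_prop_p <- function(n_total, n_class, n_response, n_both) {
  lo <- max(0, n_class + n_response - n_total)
  hi <- min(n_class, n_response)
  k <- lo:hi
  logp <- lchoose(n_response, k) + lchoose(n_total - n_response, n_class - k) -
    lchoose(n_total, n_class)
  pmf <- exp(logp - max(logp))
  pmf <- pmf / sum(pmf)
  p_hi <- sum(pmf[k >= n_both])
  p_lo <- sum(pmf[k <= n_both])
  min(1, 2 * min(p_hi, p_lo))
}

# All attainable complete category scores under the default score config.
attainable_scores <- function(good = 25, medium = 12.5, bad = 1) {
  vals <- c(bad, medium, good)
  combos <- expand.grid(vals, vals, vals, vals)
  sort(unique(rowSums(combos)))
}
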