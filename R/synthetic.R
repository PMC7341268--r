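# Seeded generator of synthetic EARS record populations.
#
# Demography is deterministic: stratum counts are taken verbatim from the
# config and equids are apportioned to kilns and handlers by largest
# remainder. Only the indicator responses are random, drawn per
# (stratum, question[, class]) block from its own counter-based RNG stream,
# so draws for one block do not depend on the sizes of other blocks.

#' Build a synthetic population configuration
#'
#' @param strata Tibble with columns `district`, `species`, `sex`,
#'   `age_category`, `work_type`, `count` and optionally `assessed`
#'   (default `TRUE`; unassessed strata get demography but no responses,
#'   emulating groups excluded for lack of data).
#' @param kilns Tibble with columns `district`, `n_kilns`. Kiln sizes are
#'   allocated by largest remainder and must land in the plausible range
#'   8-64 equids per kiln.
#' @param handlers Tibble with columns `district`, `n_handlers`.
#' @param marginals Tibble with columns `question_id`, `species` (`NA`
#'   applies to all species), `response`, `prob`. Single-select vectors are
#'   renormalised to sum to 1 (rounding repair); multi-select per-response
#'   probabilities may sum past 1, in which case individuals select one or
#'   two distinct responses so the per-response selection rate matches
#'   `prob`. Questions with no marginal rows are left unanswered.
#' @param hooks Dependence hooks: see [add_class_effect()].
#' @param seed Default seed used by [generate_population()].
#' @param schema A [wag_schema()].
#' @return A list of class `wag_synth_config`.
#' @export
synth_config <- function(strata, kilns, handlers, marginals,
                         hooks = NULL, seed = 1L, schema = wag_schema()) {
  cfg <- structure(
    list(
      strata = as_tibble(strata), kilns = as_tibble(kilns),
      handlers = as_tibble(handlers), marginals = as_tibble(marginals),
      hooks = if (is.null(hooks)) .empty_hooks() else as_tibble(hooks),
      seed = as.integer(seed), schema = schema
    ),
    class = "wag_synth_config"
  )
  if (!"assessed" %in% names(cfg$strata)) cfg$strata$assessed <- TRUE
  cfg$marginals <- .normalise_marginals(cfg$marginals, schema)
  .validate_synth_config(cfg)
  cfg
}

.empty_hooks <- function() {
  tibble(class_question = character(), class_value = character(),
         question_id = character(), response = character(),
         boost_pct = numeric())
}

#' Plant a class-dependent response shift
#'
#' Adds a dependence hook to a synthetic config: inside the given class
#' (records whose `class_question` response equals `class_value`), the
#' probability of `response` to `question_id` is raised by `boost_pct`
#' percentage points, with the other responses scaled down proportionally.
#' Used to create a non-null regime for [describe_class()].
#'
#' @param cfg A [synth_config()].
#' @param class_question,class_value The class defining the affected records.
#' @param question_id,response The target response to boost.
#' @param boost_pct Percentage-point increase (default 20).
#' @return The modified config.
#' @export
add_class_effect <- function(cfg, class_question, class_value,
                             question_id, response, boost_pct = 20) {
  stopifnot(inherits(cfg, "wag_synth_config"))
  cfg$hooks <- bind_rows(cfg$hooks, tibble(
    class_question = class_question, class_value = class_value,
    question_id = question_id, response = response, boost_pct = boost_pct
  ))
  .validate_synth_config(cfg)
  cfg
}

# Renormalise single-select probability vectors to sum exactly to 1.
.normalise_marginals <- function(marginals, schema) {
  multi <- schema$question_id[schema$multiselect]
  marginals %>%
    group_by(.data$question_id, .data$species) %>%
    mutate(prob = if (first(.data$question_id) %in% multi) .data$prob
           else .data$prob / sum(.data$prob)) %>%
    ungroup()
}

.validate_synth_config <- function(cfg) {
  fail <- function(path, msg) {
    abort(paste0("invalid synthetic config at ", path, ": ", msg),
          class = "wag_config_error")
  }
  st <- cfg$strata
  need <- c("district", "species", "sex", "age_category", "work_type", "count")
  if (!all(need %in% names(st))) fail("strata", "missing columns")
  if (any(st$count <= 0 | st$count != floor(st$count))) {
    fail("strata$count", "counts must be positive integers")
  }
  for (f in names(.demographic_vocab)) {
    if (f %in% names(st) && !all(st[[f]] %in% .demographic_vocab[[f]])) {
      fail(paste0("strata$", f), "value outside vocabulary")
    }
  }
  for (d in unique(st$district)) {
    total <- sum(st$count[st$district == d])
    nk <- cfg$kilns$n_kilns[cfg$kilns$district == d]
    if (length(nk) != 1) fail("kilns", paste0("no kiln count for ", d))
    if (total < 8 * nk || total > 64 * nk) {
      fail("kilns$n_kilns", paste0(d, ": ", total, " equids cannot fill ",
                                   nk, " kilns of 8-64"))
    }
    nh <- cfg$handlers$n_handlers[cfg$handlers$district == d]
    if (length(nh) != 1 || nh < 1) fail("handlers", paste0("need handlers for ", d))
  }
  lv <- .schema_levels(cfg$schema)
  m <- cfg$marginals
  if (any(m$prob < 0)) fail("marginals$prob", "negative probability")
  bad <- dplyr::anti_join(m, lv, by = c("question_id", "response"))
  if (nrow(bad) > 0) {
    fail("marginals", paste0("unknown question/response: ",
                             bad$question_id[1], "='", bad$response[1], "'"))
  }
  sums <- m %>%
    group_by(.data$question_id, .data$species) %>%
    summarise(total = sum(.data$prob), .groups = "drop") %>%
    left_join(cfg$schema %>% select("question_id", "multiselect"),
              by = "question_id")
  off <- sums %>% filter(!.data$multiselect, abs(.data$total - 1) > 1e-9)
  if (nrow(off) > 0) {
    fail(paste0("marginals[", off$question_id[1], "]"),
         "single-select probabilities must sum to 1")
  }
  h <- cfg$hooks
  if (nrow(h) > 0) {
    if (any(!h$question_id %in% cfg$schema$question_id) ||
        any(!h$class_question %in% cfg$schema$question_id)) {
      fail("hooks", "unknown question id")
    }
    if (any(h$question_id == h$class_question)) {
      fail("hooks", "a hook cannot target its own class question")
    }
  }
  invisible(cfg)
}

# Effective marginal for one (question, species); NULL when undefined.
.marginal_for <- function(cfg, qid, species) {
  m <- cfg$marginals[cfg$marginals$question_id == qid, ]
  if (nrow(m) == 0) return(NULL)
  sub <- m[!is.na(m$species) & m$species == species, ]
  if (nrow(sub) == 0) sub <- m[is.na(m$species), ]
  if (nrow(sub) == 0) return(NULL)
  vocab <- cfg$schema$levels[[match(qid, cfg$schema$question_id)]]$response
  p <- setNames(rep(0, length(vocab)), vocab)
  p[sub$response] <- sub$prob
  p
}

# Shift p[response] by +boost (probability scale), scaling the other entries
# to keep the total mass constant.
.boost_marginal <- function(p, response, boost) {
  total <- sum(p)
  new_r <- min(p[response] + boost, total)
  others <- setdiff(names(p), response)
  denom <- total - p[response]
  if (denom > 0) p[others] <- p[others] * (total - new_r) / denom
  p[response] <- new_r
  p
}

# Draw n response cells for one block. With total mass <= 1 each individual
# selects exactly one response; with total > 1, a second distinct response
# is added with probability total - 1 (never alongside an exclusive
# response), so per-response selection rates match the configured mass.
.draw_cells <- function(n, vocab, p, exclusive, delim, seed) {
  if (n == 0) return(character(0))
  total <- sum(p)
  if (total <= 0) return(rep(NA_character_, n))
  .with_seed(seed, {
    p1 <- p / total
    idx1 <- sample.int(length(vocab), n, replace = TRUE, prob = p1)
    cells <- vocab[idx1]
    if (total > 1 + 1e-9) {
      pi2 <- min(1, total - 1)
      second <- rbinom(n, 1, pi2) == 1
      if (!is.na(exclusive)) second <- second & vocab[idx1] != exclusive
      idx2 <- rep(NA_integer_, n)
      todo <- which(second)
      while (length(todo) > 0) {
        cand <- sample.int(length(vocab), length(todo), replace = TRUE,
                           prob = p1)
        ok <- cand != idx1[todo]
        if (!is.na(exclusive)) ok <- ok & vocab[cand] != exclusive
        idx2[todo[ok]] <- cand[ok]
        todo <- todo[!ok]
      }
      has2 <- !is.na(idx2)
      lo <- pmin(idx1[has2], idx2[has2])
      hi <- pmax(idx1[has2], idx2[has2])
      cells[has2] <- paste(vocab[lo], vocab[hi], sep = delim)
    }
    cells
  })
}

#' Generate a synthetic EARS population
#'
#' Materialises a [synth_config()] into a record tibble: exact per-stratum
#' counts, deterministic kiln and handler assignment, and seeded response
#' draws. The same config and seed always yield an identical record set,
#' and changing one stratum's count leaves the draws of other strata
#' unchanged.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A record tibble accepted by [validate_records()] with zero
#'   issues.
#' @export
generate_population <- function(cfg, seed = cfg$seed) {
  .validate_synth_config(cfg)
  schema <- cfg$schema
  delim <- .schema_delimiter(schema)
  seed <- as.integer(seed)

  st <- cfg$strata %>% mutate(stratum_idx = row_number())
  records <- st %>%
    tidyr::uncount(.data$count, .remove = FALSE) %>%
    select("stratum_idx", "district", "species", "sex", "age_category",
           "work_type", "assessed")

  # kiln and handler assignment, per district, deterministic
  records$kiln_id <- NA_character_
  records$handler_id <- NA_character_
  for (d in unique(cfg$kilns$district)) {
    rows <- which(records$district == d)
    if (length(rows) == 0) next
    nk <- cfg$kilns$n_kilns[cfg$kilns$district == d]
    nh <- cfg$handlers$n_handlers[cfg$handlers$district == d]
    prefix <- toupper(substr(d, 1, 3))
    kiln_ids <- sprintf("%s-K%02d", prefix, seq_len(nk))
    sizes <- .largest_remainder(length(rows), rep(1, nk))
    records$kiln_id[rows] <- rep(kiln_ids, sizes)
    handler_ids <- sprintf("%s-H%03d", prefix, seq_len(nh))
    per_kiln <- .largest_remainder(nh, rep(1, nk))
    start <- cumsum(c(0, per_kiln[-nk]))
    for (k in seq_len(nk)) {
      krows <- rows[records$kiln_id[rows] == kiln_ids[k]]
      hk <- handler_ids[start[k] + seq_len(max(per_kiln[k], 1))]
      if (per_kiln[k] == 0) hk <- handler_ids[1]
      records$handler_id[krows] <- rep_len(hk, length(krows))
    }
  }
  records$equid_id <- sprintf("EQ%05d", seq_len(nrow(records)))

  # responses: class questions of any hook first, then schema order
  class_qs <- unique(cfg$hooks$class_question)
  qorder <- c(class_qs, setdiff(schema$question_id, class_qs))
  for (qid in qorder) {
    qi <- match(qid, schema$question_id)
    vocab <- schema$levels[[qi]]$response
    exclusive <- schema$exclusive[qi]
    col <- rep(NA_character_, nrow(records))
    hooks_q <- cfg$hooks[cfg$hooks$question_id == qid, ]
    for (si in seq_len(nrow(st))) {
      if (!st$assessed[si]) next
      rows <- which(records$stratum_idx == si)
      if (length(rows) == 0) next
      p <- .marginal_for(cfg, qid, st$species[si])
      if (is.null(p)) next
      if (nrow(hooks_q) == 0) {
        col[rows] <- .draw_cells(length(rows), vocab, p, exclusive, delim,
                                 .stream_seed(seed, si, qi))
      } else {
        cq <- hooks_q$class_question[1]
        cls <- records[[cq]][rows]
        class_vocab <- schema$levels[[match(cq, schema$question_id)]]$response
        hooked_vals <- hooks_q$class_value
        base_rows <- rows[is.na(cls) | !cls %in% hooked_vals]
        col[base_rows] <- .draw_cells(length(base_rows), vocab, p, exclusive,
                                      delim, .stream_seed(seed, si, qi))
        for (hv in hooked_vals) {
          hrows <- rows[!is.na(cls) & cls == hv]
          hook <- hooks_q[hooks_q$class_value == hv, ][1, ]
          p_adj <- .boost_marginal(p, hook$response, hook$boost_pct / 100)
          ci <- match(hv, class_vocab)
          col[hrows] <- .draw_cells(length(hrows), vocab, p_adj, exclusive,
                                    delim, .stream_seed(seed, si, qi, ci))
        }
      }
    }
    records[[qid]] <- col
  }

  records %>%
    select(all_of(c(.demographic_cols, schema$question_id)))
}

#' Brick-kiln survey mimic configuration
#'
#' The shipped study-condition configuration: 2,448 equids (55 donkeys,
#' 1,365 horses, 1,028 mules) at 41 brick kilns in two Nepalese districts
#' (24 kilns / 1,440 equids in Dhading, 17 kilns / 1,008 in Lalitpur)
#' worked by 126 handlers (58 + 68). Per-species response marginals equal
#' the published survey percentages (renormalised where a printed column
#' does not sum to 100). Sex, age and work-type mixes follow the survey's
#' qualitative ordering (geldings > stallions > females; young adults most
#' frequent; pack > vehicle); foal strata are generated unassessed so they
#' drop out of aggregation for lack of data, as in the survey. The two main
#' questions the survey could not answer in the field (fibre availability,
#' age started working) carry no marginals and stay unanswered, so scoring
#' falls back to their alternates.
#'
#' @param seed Default seed for [generate_population()].
#' @return A [synth_config()].
#' @examples
#' cfg <- brick_kiln_config(seed = 42)
#' pop <- generate_population(cfg)
#' nrow(pop)
#' @export
brick_kiln_config <- function(seed = 1L) {
  species_counts <- c(donkey = 55, horse = 1365, mule = 1028)
  district_share <- c(Dhading = 1440, Lalitpur = 1008)
  sex_share <- c(female = 0.15, gelding = 0.55, `jack/stallion/entire` = 0.30)
  age_share <- c(foal = 0.02, juvenile = 0.15, `young adult` = 0.45,
                 adult = 0.28, geriatric = 0.10)
  work_share <- c(pack = 0.65, vehicle = 0.35)

  split_counts <- function(count, shares) {
    n <- .largest_remainder(count, unname(shares))
    tibble(value = names(shares), count = n) %>% filter(.data$count > 0)
  }

  strata <- list()
  for (sp in names(species_counts)) {
    by_district <- split_counts(species_counts[[sp]], district_share)
    for (i in seq_len(nrow(by_district))) {
      by_sex <- split_counts(by_district$count[i], sex_share)
      for (j in seq_len(nrow(by_sex))) {
        by_age <- split_counts(by_sex$count[j], age_share)
        for (k in seq_len(nrow(by_age))) {
          by_work <- split_counts(by_age$count[k], work_share)
          strata[[length(strata) + 1]] <- tibble(
            district = by_district$value[i], species = sp,
            sex = by_sex$value[j], age_category = by_age$value[k],
            work_type = by_work$value, count = by_work$count
          )
        }
      }
    }
  }
  strata <- bind_rows(strata) %>%
    mutate(assessed = .data$age_category != "foal")

  marg_path <- system.file("extdata", "brick_kiln_marginals.csv",
                           package = "wagr")
  marginals <- readr::read_csv(marg_path, show_col_types = FALSE,
                               progress = FALSE) %>%
    tidyr::pivot_longer(c("donkey", "horse", "mule"),
                        names_to = "species", values_to = "pct") %>%
    mutate(prob = .data$pct / 100) %>%
    select("question_id", "species", "response", "prob")

  synth_config(
    strata = strata,
    kilns = tibble(district = c("Dhading", "Lalitpur"), n_kilns = c(24L, 17L)),
    handlers = tibble(district = c("Dhading", "Lalitpur"),
                      n_handlers = c(58L, 68L)),
    marginals = marginals,
    seed = seed
  )
}

#' Small demonstration configuration
#'
#' A compact single-district population with uniform response marginals over
#' every question's vocabulary; useful for examples and tests.
#'
#' @param n Number of equids (>= 8).
#' @param seed Default seed.
#' @return A [synth_config()].
#' @export
demo_config <- function(n = 100, seed = 1L) {
  stopifnot(n >= 8)
  schema <- wag_schema()
  half <- floor(n / 2)
  strata <- tibble(
    district = "Dhading",
    species = c("horse", "mule"),
    sex = c("gelding", "female"),
    age_category = c("young adult", "adult"),
    work_type = c("pack", "vehicle"),
    count = c(half, n - half)
  )
  marginals <- .schema_levels(schema) %>%
    group_by(.data$question_id) %>%
    mutate(prob = 1 / n(), species = NA_character_) %>%
    ungroup() %>%
    select("question_id", "species", "response", "prob")
  n_kilns <- max(1L, ceiling(n / 50))
  synth_config(
    strata = strata,
    kilns = tibble(district = "Dhading", n_kilns = n_kilns),
    handlers = tibble(district = "Dhading",
                      n_handlers = max(2L, n_kilns * 2L)),
    marginals = marginals,
    seed = seed, schema = schema
  )
}

#' Check empirical marginals against a configuration
#'
#' Compares the per-response selection rates in a generated population with
#' the rates its config targets, pooling strata by their counts. Deviations
#' beyond three binomial standard errors are flagged.
#'
#' @param records A population from [generate_population()].
#' @param cfg The [synth_config()] it was generated from (or any config to
#'   test against).
#' @return A tibble with one row per question: `question_id`, `n` answered,
#'   `max_abs_dev_pct` (largest |empirical - configured| in percentage
#'   points), `flagged`.
#' @export
marginal_check <- function(records, cfg) {
  schema <- cfg$schema
  delim <- .schema_delimiter(schema)
  st <- cfg$strata
  out <- list()
  for (qi in seq_len(nrow(schema))) {
    qid <- schema$question_id[qi]
    vocab <- schema$levels[[qi]]$response
    expected <- setNames(rep(0, length(vocab)), vocab)
    n_expected <- 0
    for (si in seq_len(nrow(st))) {
      if (!st$assessed[si]) next
      p <- .marginal_for(cfg, qid, st$species[si])
      if (is.null(p)) next
      total <- sum(p)
      rate <- if (total > 1 + 1e-9) p else p / total
      expected <- expected + st$count[si] * rate
      n_expected <- n_expected + st$count[si]
    }
    cells <- records[[qid]]
    answered <- cells[!is.na(cells)]
    n <- length(answered)
    if (n == 0 || n_expected == 0) {
      out[[length(out) + 1]] <- tibble(question_id = qid, n = n,
                                       max_abs_dev_pct = NA_real_,
                                       flagged = FALSE)
      next
    }
    expected <- expected / n_expected
    sel <- unlist(strsplit(answered, delim, fixed = TRUE))
    emp <- table(factor(sel, levels = vocab)) / n
    dev <- abs(as.numeric(emp) - expected)
    se <- sqrt(pmax(expected * (1 - pmin(expected, 1)), 1e-12) / n)
    out[[length(out) + 1]] <- tibble(
      question_id = qid, n = n,
      max_abs_dev_pct = 100 * max(dev),
      flagged = any(dev > 3 * se)
    )
  }
  bind_rows(out)
}
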