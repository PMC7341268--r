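# Internal helpers shared across modules.

# Canonical key for vocabulary matching: case-insensitive, whitespace-trimmed,
# internal whitespace collapsed, unicode dashes mapped to "-" and spacing
# around dashes removed. Field-collected survey exports are noisy in exactly
# these ways.
.match_key <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[–—]", "-", x)
  x <- gsub("\\s+", " ", x)
  gsub(" ?- ?", "-", x)
}

# Largest-remainder (Hamilton) apportionment of `total` into integer counts
# proportional to `weights`; ties broken by position. Deterministic.
.largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- total * weights / sum(weights)
  counts <- floor(quota)
  short <- total - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Counter-based stream seed: injective in `key` for fixed `seed` because
# 2147483647 is prime and 48271 is coprime to it. Keeps every derived seed
# in 32-bit range and makes draws for one (stratum, question, class) block
# independent of the sizes of other blocks.
.stream_seed <- function(seed, stratum_idx, question_idx, class_idx = 0L) {
  key <- stratum_idx + 10001 * (question_idx + 101 * class_idx)
  s <- (seed %% 2147483647 + key * 48271) %% 2147483647
  if (s == 0) s <- 1
  as.integer(s)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.level_factor <- function(x) {
  factor(x, levels = .wag_levels, ordered = TRUE)
}

# Worst (i.e. lowest) of a set of welfare levels; NA if none.
.worst_level <- function(levels) {
  f <- .level_factor(levels)
  f <- f[!is.na(f)]
  if (length(f) == 0) NA_character_ else as.character(min(f))
}
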