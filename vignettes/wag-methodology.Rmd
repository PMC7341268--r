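---
title: "Grading working-equid welfare: the WAG aggregation model in wagr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading working-equid welfare: the WAG aggregation model in wagr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wagr)
library(dplyr)
```

## The problem

Welfare assessments of working equids — donkeys, horses and mules carrying
bricks, goods and water in low- and middle-income settings — collect dozens
of animal- and resource-based indicators per animal (body condition,
lameness, skin lesions, water access, housing, handling). Field teams and
NGOs need these turned into a small number of comparable, decision-ready
summaries: which welfare domain is worst, for which demographic group, and
which indicator is driving it.

`wagr` implements the Welfare Aggregation and Guidance (WAG) approach over
EARS-style questionnaire records (Equid Assessment, Research and Scoping: a
standardised welfare survey instrument). Each of five welfare categories —
nutrition, health, behaviour, housing, working conditions — is measured by
four main indicator questions, some with a designated alternate used when
the main question cannot be answered in the field.

## The grading model

Scoring proceeds in three steps.

**1. Response → welfare level → points.** Every response string maps to a
welfare level *good*, *medium* or *bad* via the shipped schema
(`wag_schema()`). Levels convert to points: good = 25, medium = 12.5,
bad = 1 (`score_config()`). The deliberately asymmetric *bad* score keeps a
single bad answer visible in the category sum: three good answers plus one
bad give 76, not the 87.5 a linear scale would give.

For multi-select questions (e.g. skin alterations, where one animal may
show scars *and* open wounds), the package scores the **worst** selected
response. The instrument's own per-individual rule for multiple findings is
not published; worst-of is the conservative choice consistent with the
protective intent of welfare grading, and `welfare_level()` guarantees that
recording an additional finding can never raise the level.

**2. Category score per equid.** The four main-question points are summed,
giving a score in [4, 100] (`score_records()`). If a main question is
unanswered and its alternate is answered, the alternate substitutes (and is
recorded in `alternates_used`); the two substitutions the instrument
documents are fibre availability → presence of a clean water point while
housed, and age started working → access to shade during breaks. If neither
main nor alternate is answered the category is *incomplete* for that equid:
no score is imputed, and the animal is excluded from that category's
population aggregation (with the exclusion counted). Scores bin into ten
letter grades, J (1–10, worst) to A (90–100, best), as half-open width-10
intervals `(lower, upper]` — the only contiguous partition consistent with
the published endpoints J = 1–10 and A = 90–100.

**3. Population grade.** For a group of equids, bin percentages are
accumulated from J upward and the population grade is the first (worst)
grade at which the cumulative percentage reaches the threshold
(`population_grade()`, default `threshold_pct = 15`). This worst-first rule
is intentionally pessimistic: a 15% tail of very poor animals determines
the group's grade no matter how good the majority is. The threshold
comparison is made on integer counts (`cum_count * 100 >= threshold * n`),
so a population with exactly 15 of 100 animals in bin J grades J and one
with 14 does not — no floating-point edge cases.

```{r pop-grade}
pg <- population_grade(data.frame(score = c(rep(4, 15), rep(100, 85))))
glance(pg)
```

`grade_matrix()` repeats this per stratum (overall, district, sex, species,
age category, work type) and per category. Strata with fewer than
`min_stratum_n = 5` complete scores are reported as excluded rather than
graded — surveys routinely drop sparsely assessed groups such as foals "for
lack of data", and 5 is the smallest group for which a 15% tail is even
representable. Individuals are unweighted: no kiln- or handler-clustering
weights are applied, as the source methodology defines none.

## Drivers and response tables

`driver_report()` ranks a category's four question slots by the percentage
of individuals at *bad* (primary key) then *medium* (secondary key),
identifying the indicator responsible for a poor grade. `response_table()`
reproduces the survey-table layout: per-species and overall percentages of
each response among answered individuals; for multi-select questions an
individual counts once per selected response, so columns may exceed 100%.
Percentages are computed unrounded; any rounding (reports use one decimal)
happens at presentation only, never before grading.

## Describing handler-attitude classes

To link handler attitude to welfare indicators the package uses categorical
class description: for every (class value, question, response) triple it
compares the class-conditional response proportion with the global
proportion. Under the null that class membership is independent of the
response, the joint count follows the central hypergeometric law, so
`two_prop_test()` reports

* `p_value` — the doubled smaller exact tail, capped at 1 (exactness
  matters here: some attitude classes are tiny), and
* `statistic` — the signed standard-normal quantile of the one-sided
  *mid-p* (half the probability of the observed table attributed to the
  tail), positive for enrichment. The mid-p construction makes the
  statistic nearly calibrated on the normal scale despite discreteness;
  both quantities are computed on the log scale so extreme enrichments
  stay finite, and p-values are clamped above zero at the smallest
  representable double.

`describe_class()` runs this for every response of every target question
(multi-select responses as presence/absence indicators), excludes records
missing the class variable, retains entries with `p_value <= alpha`
(raw p-values by default, matching the narrative reporting style; optional
Benjamini–Hochberg via `bh = TRUE`), and sorts by descending `|statistic|`
within class. A consequence of using the *exact* doubled-tail p-value worth
knowing: it is conservative. Under a simulated independence null at
n = 2,448 the fraction of tests with p ≤ 0.05 is ≈ 4.4%, not 5.0% — the
achievable tail probabilities near 0.025 are spaced by the hypergeometric
point mass at the critical value, so an exact test cannot reject at
exactly the nominal rate. The mid-p statistic, by contrast, exceeds 1.96
in ≈ 5.0% of null tests. Users wanting calibrated screening should gate on
`|statistic|`; users wanting guaranteed type-I control should gate on
`p_value`.

## The synthetic population generator

The study populations this method is applied to are rarely deposited, so
the package ships a seeded generator (`synth_config()`,
`generate_population()`) and a mimic configuration of a published survey
of Nepalese brick kilns (`brick_kiln_config()`):

* **Demography is deterministic.** Stratum counts are taken verbatim from
  the config; the mimic reproduces the printed census exactly — 2,448
  equids (55 donkeys, 1,365 horses, 1,028 mules) at 41 kilns (24 in
  Dhading with 1,440 equids, 17 in Lalitpur with 1,008) worked by 126
  handlers (58 + 68). Equids are apportioned to kilns and handlers by
  largest-remainder allocation. The survey's printed kiln-size dispersion
  (min 8, mean 33) is arithmetically inconsistent with its own totals
  (2,448/41 ≈ 60), so the generator honours the totals and the 8–64
  feasibility range, yielding near-uniform sizes around 60.
* **Unprinted mixes are fixed once.** Sex (15% female, 55% gelding, 30%
  stallion), age (2% foal, 15% juvenile, 45% young adult, 28% adult, 10%
  geriatric) and work type (65% pack, 35% vehicle) follow the survey's
  qualitative ordering of its demography figures; the district split
  (1,440/1,008) keeps kiln sizes feasible.
* **Responses are drawn per question from per-species marginals** equal to
  the printed percentages, renormalised where a printed column does not
  sum to 100 (rounding, or a truncated feed list). The printed per-species
  columns of the nominally multi-select questions each sum to ~100%,
  i.e. one recorded response per animal, so the mimic samples one
  categorical draw per question. For configs whose per-response mass sums
  past 1 the sampler adds a second distinct response with the excess
  probability, never alongside an exclusive "no findings" response.
* **Lack of data is modelled, not hard-coded.** Foal strata are generated
  `assessed = FALSE` (demography present, responses missing), so foals
  drop out of aggregation through the ordinary completeness rule, exactly
  as a sparsely assessed group would in real data. Likewise the two
  replaced main questions carry no marginals and stay unanswered, forcing
  the alternate-substitution path.
* **Seeding is counter-based.** Each (stratum, question, class) block draws
  from its own stream derived injectively from the seed, so the same seed
  reproduces a population byte for byte and resizing one stratum leaves
  every other stratum's draws unchanged. `marginal_check()` compares
  empirical against configured marginals and flags deviations beyond three
  binomial standard errors.
* **Dependence hooks** (`add_class_effect()`) shift one response's
  probability inside one class, creating the non-null regime needed to
  exercise `describe_class()`; everything else stays independent across
  questions, because only marginals are published.

What passing tests on this generator do **not** show: real survey data have
cross-question dependence (a thin, lame animal is likelier to also have
wounds), kiln-level clustering, and enumerator effects, none of which the
generator emulates. Population grades are tail-sensitive, so independence
tends to *understate* the worst-bin mass relative to a positively dependent
reality. Under the mimic configuration the overall nutrition grade computes
to G at most seeds (occasionally F: the cumulative percentage at G sits
essentially on the 15% threshold), in line with the survey's published G;
the test suite reports this figure rather than asserting it, since the true
joint distribution is unknown.

## Numerical and design choices

* Vocabulary matching is case-insensitive, whitespace-trimmed, and
  dash-normalised; values are stored canonically as in the schema. Missing
  responses are empty CSV cells, represented as `NA`, never `""`.
* The multi-select cell delimiter is `";"` (commas delimit fields).
* Grade comparisons never use rounded percentages; ties in driver ranking
  break by schema order (stable); ties in class-description ranking break
  by statistic sign, then question and response.
* `threshold_pct`, `min_stratum_n`, `alpha`, the score points and the grade
  scale are all configurable; defaults are the published constants.
* Problem sizes in the test suite (populations up to 500 for oracle
  equivalence, 1,000 null replicates at n = 2,448 for test calibration,
  200 replicates for planted-effect recovery) were chosen to make binomial
  Monte-Carlo error small relative to the margins being checked.

## Known limitations

* Whether any WAG question uses conditional logic across questions (the
  original decision trees) is not recoverable from the published method;
  the package implements per-question lookup plus worst-of.
* The overall grade row aggregates per-category completeness (an equid
  incomplete in housing still contributes to nutrition); whether the
  original analysis did the same is unstated.
* Exact-test conservatism (above) is a property of the published
  reporting convention, not a bug; it is quantified, not hidden.
* The generator's independence assumption bounds what the mimic can
  reproduce: printed marginal tables yes, joint-distribution-dependent
  quantities (like the exact published grade matrix) no.
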