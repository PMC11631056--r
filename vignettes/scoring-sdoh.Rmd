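---
title: "Scoring the All of Us Social Determinants of Health Survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the All of Us Social Determinants of Health Survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdohscores)
library(dplyr)
```

## The problem

The *All of Us* Research Program's optional Social Determinants of Health
Survey combines 80 items from established instruments to evaluate 14
constructs — neighborhood cohesion, disorder, and built environment; social
support; loneliness; everyday and medical-settings discrimination; food and
housing insecurity; housing quality; perceived stress; daily spiritual
experiences; religious service attendance; and English proficiency.
Responses are exported from the Researcher Workbench as a long table, one
row per participant-item, with coded answers. Before any analysis the items
must be relabelled, reverse-coded where the instrument requires it, and
reduced to construct scores — and several constructs have more than one
published scoring convention.

`sdohscores` packages that whole pipeline: a machine-readable registry of
the survey's structure, an ingest step from the long export format, all 30
scoring options (multiple options for 8 of the 14 constructs), internal
consistency reporting, and a synthetic-cohort generator so the entire system
is testable outside the controlled-access environment.

## The registry

Everything is driven by the registry: for each item it records the construct,
the response vocabulary (each answer code's numeric value or retained
category label), the scale bounds, and the polarity; for each scoring option
it records the reducer, the required items, and the printed score range.

```{r}
reg <- sdoh_registry()
reg
count(filter(reg$items, counted), construct)
```

The registry uses deterministic placeholder codes (`SDOH_COHESION_1`,
`AGREE5_4`, ...) because the Workbench's concept identifiers are part of the
controlled-access environment. A YAML config passed to `load_registry()`
rebinds question and answer codes to real concept IDs without touching any
scoring logic, and can also override item polarities or the chronicity map.
`write_registry()`/`read_registry()` round-trip the whole registry through
YAML so it can be dumped, audited, edited and reloaded.

Two structural choices deserve a note, since the survey documentation leaves
them open:

* **Disorder polarity.** The 13 disorder items mix disorder-oriented and
  order-oriented statements. The registry defaults to the source
  instrument's polarity (reverse-scoring "My neighborhood is clean",
  "People ... take good care of their houses and apartments", "My
  neighborhood is safe", and "People ... watch out for each other") and the
  `reversed_items` config key exists precisely so users can rebind this if
  their item set differs.
* **The 30-option partition.** The option catalogue is: cohesion 1;
  disorder 3 (total, physical, social); environment 3 (PANES total, NEI,
  crime safety); social support 3 (overall, instrumental, emotional);
  loneliness 1; everyday discrimination 4 (situation, frequency, chronicity,
  main-reason relabel); medical-settings discrimination 4 (never-ever,
  count, sum, average); food insecurity 1; housing insecurity 1; housing
  quality 1; perceived stress 2 (total, category); spiritual experiences 2
  (standard, nonbelief-zero); religious attendance 1; English proficiency 3.
  That is 30 options with multiple options for exactly 8 constructs, and the
  registry makes the partition explicit and checkable rather than implicit
  in a pile of functions.

## Scoring rules and their parameters

All scores follow the same complete-case contract: a participant missing any
item required by a score receives `NA` for that score but remains in every
output table. No imputation or prorating is performed anywhere — that is a
deliberate non-goal, and the `NA`s are the signal telling you where a
missing-data strategy would have to act.

The reducers themselves:

| Construct | Options | Rule | Range |
|---|---|---|---|
| Cohesion | mean | mean of 4 items (1–5 agree scale) | 1–5 |
| Disorder | total / physical / social | mean of 13 / 6 / 7 items after aligning order items | 1–4 |
| Environment | PANES total | sum of 7 Likert items, crime items reversed | 7–28 |
| | NEI | count of favorable responses over 6 items | 0–6 |
| | crime safety | sum of the 2 reversed crime items | 2–8 |
| Social support | overall / instrumental / emotional | 100·(mean − 1)/4 | 0–100 |
| Loneliness | total | sum of 8 items, 2 positive items reversed | 8–32 |
| Everyday discrimination | situation | count of items ever experienced | 0–9 |
| | frequency | raw sum | 9–54 |
| | chronicity | annualized events, summed | 0–2340 |
| Medical-settings discrimination | never-ever / count / sum / average | any-vs-none, count of ever items, sum, mean | —, 0–7, 7–35, 1–5 |
| Food insecurity | screen | either item often/sometimes true | binary |
| Housing insecurity | screen | ≥ 2 moves in the past year | binary |
| Housing quality | screen | any problem except "None of the above" | binary |
| Perceived stress | total / category | sum of 10 items, 4 positive items reversed; cut at 0–13 / 14–26 / 27–40 | 0–40 |
| Spiritual experiences | standard / nonbelief-zero | sum of 6 items; added nonbelief options valued 1 or 0 | 6–36 / 2–36 |
| Religious attendance | relabel | ordered frequency, "I am not religious" kept separate | categorical |
| English proficiency | binary / ordinal / collapsed | gate item; proficiency level; proficient / not proficient / unknown | categorical |

A few parameter choices are genuinely open and were fixed once, as follows:

* **Chronicity map.** Only the top category is anchored publicly: "almost
  every day" counts as 5 experiences per week × 52 weeks = 260 per year, and
  nine items at that category give the printed maximum 2340. The
  intermediate categories default to {never 0, less than once a year 0.5, a
  few times a year 3, a few times a month 36, at least once a week 52,
  almost every day 260} — consistent with both anchors and monotone in the
  response order — and are user-configurable (`chronicity_map` config key)
  because no published source pins them down.
* **NEI dichotomization.** Likert NEI items score 1 on the agree side (3–4
  on the 1–4 scale); the residential-density item scores 0 for detached
  single-family housing (low density) and 1 otherwise. This follows the
  index's "more favorable built environment" direction.
* **Crime-safety reducer.** The subscale is named in the survey literature
  without a printed reducer; the package sums the two reverse-scored items
  (range 2–8), consistent with the PANES total being a sum.
* **PANES non-substantive responses.** "Does not apply to my neighborhood"
  and "Don't know/not sure" map to missing, so under the complete-case
  contract the participant's PANES total is `NA`. Prorating over answered
  items would change the printed 7–28 range and is not done.
* **Food insecurity with one item missing** is `NA` even when the answered
  item already screens positive: the uniform complete-case contract wins
  over the screen's "either item" shortcut, keeping `NA` semantics identical
  across all 30 options.
* **Housing-quality conflicts** ("None of the above" endorsed alongside
  problems) resolve in favor of the endorsed problems, with a warning:
  affirmative evidence beats the exclusive choice.
* **Skip semantics.** "Skip", "Don't know" and "Prefer not to answer" are
  missing for every scale item. They are retained as categories only where
  a score explicitly keeps them: the English-proficiency ordinal and
  collapsed options (where "Don't know"/"Prefer not to answer" are levels,
  collapsing to "unknown"), and "I am not religious" for attendance and the
  spiritual-experiences items, which carry their own added options.
* **Duplicate rows** (the same participant answering the same non-checklist
  item twice) resolve last-wins by timestamp, then file order, with a
  warning — deterministic and logged.
* **Numerical policy.** Means are carried at full double precision; no
  rounding happens before range checks; CSV output renders `NA` as an empty
  field.

## Worked example

```{r}
fix <- fixture_participants()
calc_eds(fix, "chronicity") |> filter(person_id == "eds_worked")
```

One item at "Almost every day" contributes 5 × 52 = 260 annualized
experiences; the other eight at "Never" contribute 0.

```{r}
cohort <- generate_cohort(cohort_spec(n = 200, seed = 42))
scores <- score_all(cohort$responses)
scores_wide(scores) |> select(person_id, df_cohesion, df_pss_total,
                              df_pss_category, df_edd_chronicity) |> head()
```

## Internal consistency

For multi-item scales, `cronbach_alpha()` reports
\(\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)\)
over complete cases of the polarity-applied items, with sample (n−1)
variances throughout, plus alpha-if-item-deleted diagnostics. Reverse
scoring first is the conventional choice — without it, deliberately
negatively worded items depress the inter-item covariances and alpha is
meaningless. Preconditions are enforced, not patched: fewer than 3 complete
cases or zero total-score variance raise errors (`alpha_table()` converts
them to annotated rows instead of crashing a batch run).

```{r}
alpha_table(cohort$responses)
```

Note the alphas near zero: the default generator draws items independently,
so this is exactly what internal consistency should report on such data (and
is one of the package's test properties). No published alpha value is
reproduced here because the survey's own documentation prints none.

## What the synthetic generator does and does not emulate

`generate_cohort()` emulates the *format and logic* of the survey export:
all 80 items with their real response vocabularies, per-item missingness
(absent rows) and skip codes at configurable rates (defaults 2% each,
reflecting the low item non-response reported for the survey), the
select-all-that-apply housing checklist, and the branching
English-proficiency sub-item emitted only when the gate answer is yes. All
draws are made once, in canonical registry order, from a single seeded
stream, so a `(spec, seed)` pair reproduces the identical cohort
byte for byte.

It deliberately does **not** emulate the marginal response distributions,
inter-item correlations, or demographic structure of the real cohort. Item
values are drawn independently (centre-peaked for Likert items, uniform for
categorical items, geometric for the move count, 15% endorsement per housing
problem). Consequently, passing tests demonstrate that the *scoring
machinery* is correct — value mapping, reversal, reduction, the NA contract
— not that any distributional property of real data is reproduced.
Cohort-level results from the controlled-access data (score distributions,
reliabilities by demography) are out of scope by design.

The generator's ground truth is produced by a naive scorer that works
directly off the drawn wide values with literal formulas, bypassing the
long-format pipeline entirely; the test suite holds a second, independently
written brute-force oracle. Production scores must match both, exactly, for
every seed tried — this oracle equivalence is the package's central
correctness property, alongside range conservation (no non-`NA` score ever
leaves its printed range, checked over randomized cohorts of 1,000
participants across 20 seeds) and the NA contract (verified against the
oracle on 20-person cohorts across 100 seeds). Problem sizes were chosen so
the whole suite runs in a few minutes on a laptop while still exercising
every option on thousands of participants.

## Known limitations

* English-language instrument semantics only; the Spanish versions of the
  survey have their own psychometric considerations and are not modelled.
* Complete case is the only missing-data strategy; anything else (casewise
  deletion thresholds, imputation, subset scoring) is the analyst's job,
  downstream of the `NA`s this package hands back.
* The default concept codes are placeholders until rebound to Workbench
  concept IDs with a registry config.
* Construct validity (factor structure, invariance) is out of scope;
  internal consistency is the only psychometric statistic computed.
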