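# sdohscores

Scoring tools for the *All of Us* Research Program **Social Determinants of
Health Survey**.

The survey combines **80 items from 14 established instruments** — covering
neighborhood cohesion, disorder and built environment, social support,
loneliness, everyday and medical-settings discrimination, food and housing
insecurity, housing quality, perceived stress, daily spiritual experiences,
religious service attendance, and English proficiency — and exports from the
Researcher Workbench as a long table of coded answers, one row per
participant-item. Turning that export into analyzable construct scores means
relabelling answer codes, reverse-coding negatively/positively worded items,
choosing among several published scoring conventions, and handling item
non-response consistently. This package does all of it, for researchers
working in (or preparing to work in) the Workbench:

* a machine-readable **registry** of all 14 constructs, 80 items, response
  vocabularies, item polarities, and the catalogue of **30 scoring options**
  (multiple options for 8 constructs), with YAML rebinding of the
  placeholder codes to real Workbench concept IDs;
* **ingest** of the long export CSV, answer-code → value mapping, Likert
  reverse scoring `v ↦ min + max − v`, and pivoting to participant × item
  matrices;
* all **30 scoring options** under a uniform complete-case contract:
  participants missing any required item get `NA` but stay in every output
  table;
* **internal consistency**: Cronbach's
  `α = k/(k−1) · (1 − Σ s²ᵢ / s²_T)` over complete cases of the
  polarity-applied items, with alpha-if-item-deleted, broom-style `tidy()` /
  `glance()`, and `autoplot()`;
* a **synthetic cohort generator** that emulates the export format
  (missingness, skip codes, the housing checklist, branching logic) with
  known ground truth, so the whole pipeline is testable without
  controlled-access data;
* a **command line** (`generate`, `score`, `alpha`, `registry-validate`) via
  `sdoh_cli()` and the installed `inst/scripts/sdoh` wrapper.

Example scoring rules: everyday discrimination supports situation-based
(count of situations ever experienced, 0–9), frequency-based (raw sum,
9–54), and chronicity-based scoring, which recodes each response to
annualized experiences — "almost every day" is 5/week × 52 weeks = 260/year
— and sums to 0–2340. Perceived stress sums to 0–40 with categories low
(0–13), moderate (14–26) and high (27–40) stress.

## Worked example

```r
library(sdohscores)
library(dplyr)

# a participant answering "Almost every day" on one everyday-discrimination
# item and "Never" on the other eight
fix <- fixture_participants()
calc_eds(fix, "chronicity") |> filter(person_id == "eds_worked")
#> # A tibble: 1 × 3
#>   person_id  score option_id
#>   <chr>      <dbl> <chr>
#> 1 eds_worked   260 df_edd_chronicity
```

One item at the top frequency category contributes 260 annualized
experiences (5 per week × 52 weeks); the "Never" items contribute 0.

```r
cohort <- generate_cohort(cohort_spec(n = 200, seed = 42))
scores <- score_all(cohort$responses)
scores_wide(scores) |>
  select(person_id, df_cohesion, df_pss_total, df_pss_category,
         df_edd_chronicity) |> head()
#> # A tibble: 6 × 5
#>   person_id df_cohesion df_pss_total df_pss_category df_edd_chronicity
#>   <chr>           <dbl>        <dbl> <chr>                       <dbl>
#> 1 P000001          4              NA <NA>                          NA
#> 2 P000002          3.25           24 moderate stress              670
#> 3 P000003          4.25           19 moderate stress              714.
#> 4 P000004          2.5            23 moderate stress               NA
#> 5 P000005          2.5            21 moderate stress               NA
#> 6 P000006          3.5            14 moderate stress               NA
```

`NA`s mark participants missing a required item for that particular score
(the complete-case contract): participant `P000001` skipped a stress item, so
both stress scores are `NA`, while their cohesion score is intact. Every
participant appears in every table.

```r
alpha_table(cohort$responses) |> head(3)
#> # A tibble: 3 × 5
#>   construct       k n_complete    alpha note
#>   <chr>       <int>      <int>    <dbl> <chr>
#> 1 cohesion        4        166 -0.00262 <NA>
#> 2 disorder       13        124 -0.0138  <NA>
#> 3 environment     7        151  0.215   <NA>
```

Alphas near zero are correct here: the synthetic generator draws items
independently, and internal consistency is exactly the statistic that should
notice.

From a shell, the same pipeline is:

```sh
Rscript inst/scripts/sdoh generate --n 200 --seed 42 --outdir cohort/
Rscript inst/scripts/sdoh score --input cohort/responses.csv --outdir scores/ --wide
Rscript inst/scripts/sdoh alpha --input cohort/responses.csv --out alpha.csv
```

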