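# Construct-named convenience wrappers, the calc_<construct>(dataset) surface
# researchers call interactively. Each takes the long response table first
# and returns a person_id/score tibble via the scoring engine.

.calc <- function(responses, option_id, registry) {
  score_responses(responses, option_id, registry)
}

#' Construct scoring functions
#'
#' One function per construct, following the `calc_<construct>(dataset)`
#' calling convention: each takes the long response table, selects the
#' construct's items, relabels answers, applies reverse scoring where needed,
#' computes the score over complete cases and reinserts `NA` for everyone
#' else. Constructs with several published scoring options take a `variant`
#' argument.
#'
#' * `calc_cohesion()` — mean of the 4 cohesion items (1-5).
#' * `calc_disorder()` — mean of all 13 disorder items, or of the 6-item
#'   `physical` / 7-item `social` subscales (1-4), after reverse scoring
#'   order-oriented items.
#' * `calc_panes_total()` — sum of the 7 Likert environment items (7-28),
#'   crime items reverse-scored.
#' * `calc_nei()` — Neighborhood Environment Index, 6 dichotomized items
#'   (0-6).
#' * `calc_crime_safety()` — sum of the 2 reverse-scored crime items (2-8).
#' * `calc_social_support()` — mMOS-SS item average transformed to 0-100;
#'   `overall`, `instrumental` or `emotional`.
#' * `calc_loneliness()` — ULS-8 total (8-32) after reversing the 2 positively
#'   worded items.
#' * `calc_eds()` — everyday discrimination: `situation` (0-9), `frequency`
#'   (9-54) or `chronicity` (annualized experiences/year, 0-2340).
#' * `relabel_eds_reason()` — main-reason follow-up item as a category.
#' * `calc_dms()` — discrimination in medical settings: `never_ever`
#'   (none/any), `count` (0-7), `sum` (7-35) or `average` (1-5).
#' * `calc_food_insecurity()` — Hunger Vital Sign screen (at risk / not at
#'   risk).
#' * `calc_housing_insecurity()` — at risk when moved 2+ times in the past
#'   year.
#' * `calc_housing_quality()` — housing need when any problem other than
#'   "None of the above" is endorsed.
#' * `calc_pss()` — PSS-10 `total` (0-40) or `category` (low/moderate/high
#'   stress).
#' * `calc_dses()` — daily spiritual experiences total; `standard` values the
#'   added nonbelief options 1 (range 6-36), `nonbelief_zero` values them 0
#'   (range 2-36).
#' * `calc_religious_attendance()` — attendance frequency category, with
#'   "I am not religious" kept separate.
#' * `calc_english_proficiency()` — `binary_other_language` (speaks another
#'   language at home, Yes/No), `ordinal` (proficiency level among gate-yes
#'   respondents) or `collapsed` (proficient / not proficient / unknown).
#'
#' @param responses A long response tibble ([read_responses()] or
#'   [generate_cohort()]).
#' @param variant,option Scoring variant, see above.
#' @param registry An `sdoh_registry`.
#' @return A tibble with columns `person_id`, `score`, `option_id`.
#' @examples
#' resp <- fixture_participants()
#' calc_eds(resp, "chronicity")
#' @name calc_constructs
NULL

#' @rdname calc_constructs
#' @export
calc_cohesion <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_cohesion", registry)
}

#' @rdname calc_constructs
#' @export
calc_disorder <- function(responses, variant = c("total", "physical", "social"),
                          registry = sdoh_registry()) {
  variant <- match.arg(variant)
  id <- switch(variant, total = "df_disorder",
               physical = "df_disorder_physical", social = "df_disorder_social")
  .calc(responses, id, registry)
}

#' @rdname calc_constructs
#' @export
calc_panes_total <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_panes_total", registry)
}

#' @rdname calc_constructs
#' @export
calc_nei <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_nei", registry)
}

#' @rdname calc_constructs
#' @export
calc_crime_safety <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_crime_safety", registry)
}

#' @rdname calc_constructs
#' @export
calc_social_support <- function(responses,
                                variant = c("overall", "instrumental", "emotional"),
                                registry = sdoh_registry()) {
  variant <- match.arg(variant)
  id <- switch(variant, overall = "df_support",
               instrumental = "df_support_instrumental",
               emotional = "df_support_emotional")
  .calc(responses, id, registry)
}

#' @rdname calc_constructs
#' @export
calc_loneliness <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_loneliness", registry)
}

#' @rdname calc_constructs
#' @export
calc_eds <- function(responses,
                     variant = c("situation", "frequency", "chronicity"),
                     registry = sdoh_registry()) {
  variant <- match.arg(variant)
  .calc(responses, paste0("df_edd_", variant), registry)
}

#' @rdname calc_constructs
#' @export
relabel_eds_reason <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_edd_reason", registry)
}

#' @rdname calc_constructs
#' @export
calc_dms <- function(responses,
                     variant = c("never_ever", "count", "sum", "average"),
                     registry = sdoh_registry()) {
  variant <- match.arg(variant)
  .calc(responses, paste0("df_dms_", variant), registry)
}

#' @rdname calc_constructs
#' @export
calc_food_insecurity <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_food_insecurity", registry)
}

#' @rdname calc_constructs
#' @export
calc_housing_insecurity <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_housing_insecurity", registry)
}

#' @rdname calc_constructs
#' @export
calc_housing_quality <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_housing_quality", registry)
}

#' @rdname calc_constructs
#' @export
calc_pss <- function(responses, variant = c("total", "category"),
                     registry = sdoh_registry()) {
  variant <- match.arg(variant)
  .calc(responses, paste0("df_pss_", variant), registry)
}

#' @rdname calc_constructs
#' @export
calc_dses <- function(responses, variant = c("standard", "nonbelief_zero"),
                      registry = sdoh_registry()) {
  variant <- match.arg(variant)
  id <- if (variant == "standard") "df_dses" else "df_dses_nonbelief_zero"
  .calc(responses, id, registry)
}

#' @rdname calc_constructs
#' @export
calc_religious_attendance <- function(responses, registry = sdoh_registry()) {
  .calc(responses, "df_religious_attendance", registry)
}

#' @rdname calc_constructs
#' @export
calc_english_proficiency <- function(responses,
                                     option = c("binary_other_language",
                                                "ordinal", "collapsed"),
                                     registry = sdoh_registry()) {
  option <- match.arg(option)
  id <- switch(option, binary_other_language = "df_english_binary",
               ordinal = "df_english_ordinal",
               collapsed = "df_english_collapsed")
  .calc(responses, id, registry)
}
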