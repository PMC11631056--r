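# Brute-force oracle: recomputes every scoring option person by person,
# straight from the generator's ground-truth wide values, with explicit
# loops and literal formulas. Deliberately naive and independent of the
# package's scoring engine.

oracle_scores <- function(truth, registry = REG) {
  pid <- truth[[1]]$person_id
  items_of <- function(con) {
    it <- registry$items[registry$items$construct == con, ]
    it[order(it$item_index), ]
  }
  # polarity-aligned numeric values for one person over given item rows
  aligned <- function(mat, it, i) {
    vapply(seq_len(nrow(it)), function(k) {
      v <- as.numeric(mat[[it$question_code[k]]][i])
      if (!is.na(v) && it$polarity[k] == "reversed") {
        v <- it$scale_min[k] + it$scale_max[k] - v
      }
      v
    }, numeric(1))
  }
  strict <- function(v, f) if (anyNA(v)) NA_real_ else f(v)
  per_person <- function(f) vapply(seq_along(pid), f, numeric(1))
  per_person_chr <- function(f) vapply(seq_along(pid), f, character(1))

  out <- list()
  emit <- function(id, score) {
    out[[id]] <<- tibble::tibble(person_id = pid, score = score,
                                 option_id = id)
  }

  it <- items_of("cohesion")
  emit("df_cohesion", per_person(function(i)
    strict(aligned(truth$cohesion, it, i), mean)))

  it <- items_of("disorder")
  emit("df_disorder", per_person(function(i)
    strict(aligned(truth$disorder, it, i), mean)))
  emit("df_disorder_physical", per_person(function(i)
    strict(aligned(truth$disorder, it[it$subscale == "physical", ], i), mean)))
  emit("df_disorder_social", per_person(function(i)
    strict(aligned(truth$disorder, it[it$subscale == "social", ], i), mean)))

  it <- items_of("environment")
  emit("df_panes_total", per_person(function(i)
    strict(aligned(truth$environment, it[it$item_index >= 2, ], i), sum)))
  emit("df_nei", per_person(function(i) {
    dens <- truth$environment[[it$question_code[1]]][i]
    lik <- aligned(truth$environment, it[it$item_index %in% 2:6, ], i)
    if (is.na(dens) || anyNA(lik)) return(NA_real_)
    (dens != "Detached single-family housing") + sum(lik >= 3)
  }))
  emit("df_crime_safety", per_person(function(i)
    strict(aligned(truth$environment, it[it$subscale == "crime", ], i), sum)))

  it <- items_of("social_support")
  mmos <- function(v) 100 * (mean(v) - 1) / 4
  emit("df_support", per_person(function(i)
    strict(aligned(truth$social_support, it, i), mmos)))
  emit("df_support_instrumental", per_person(function(i)
    strict(aligned(truth$social_support, it[1:4, ], i), mmos)))
  emit("df_support_emotional", per_person(function(i)
    strict(aligned(truth$social_support, it[5:8, ], i), mmos)))

  it <- items_of("loneliness")
  emit("df_loneliness", per_person(function(i)
    strict(aligned(truth$loneliness, it, i), sum)))

  it <- items_of("everyday_discrimination")
  eds9 <- it[it$item_index <= 9, ]
  emit("df_edd_situation", per_person(function(i)
    strict(aligned(truth$everyday_discrimination, eds9, i),
           function(v) sum(v > 1))))
  emit("df_edd_frequency", per_person(function(i)
    strict(aligned(truth$everyday_discrimination, eds9, i), sum)))
  cm <- registry$chronicity_map
  emit("df_edd_chronicity", per_person(function(i)
    strict(aligned(truth$everyday_discrimination, eds9, i),
           function(v) sum(unname(cm[as.character(v)])))))
  emit("df_edd_reason", per_person_chr(function(i) {
    v <- truth$everyday_discrimination[[it$question_code[10]]][i]
    if (is.na(v)) NA_character_ else as.character(v)
  }))

  it <- items_of("healthcare_discrimination")
  dmsv <- function(i) aligned(truth$healthcare_discrimination, it, i)
  emit("df_dms_never_ever", per_person_chr(function(i) {
    v <- dmsv(i)
    if (anyNA(v)) NA_character_ else if (any(v > 1)) "any" else "none"
  }))
  emit("df_dms_count", per_person(function(i)
    strict(dmsv(i), function(v) sum(v > 1))))
  emit("df_dms_sum", per_person(function(i) strict(dmsv(i), sum)))
  emit("df_dms_average", per_person(function(i) strict(dmsv(i), mean)))

  it <- items_of("food_insecurity")
  emit("df_food_insecurity", per_person_chr(function(i) {
    a <- truth$food_insecurity[[it$question_code[1]]][i]
    b <- truth$food_insecurity[[it$question_code[2]]][i]
    if (is.na(a) || is.na(b)) return(NA_character_)
    if (a %in% c("Often true", "Sometimes true") ||
        b %in% c("Often true", "Sometimes true")) "at risk" else "not at risk"
  }))

  it <- items_of("housing_insecurity")
  emit("df_housing_insecurity", per_person_chr(function(i) {
    v <- as.numeric(truth$housing_insecurity[[it$question_code[1]]][i])
    if (is.na(v)) NA_character_ else if (v >= 2) "at risk" else "not at risk"
  }))

  it <- items_of("housing_quality")
  emit("df_housing_quality", per_person_chr(function(i) {
    s <- truth$housing_quality[[it$question_code[1]]][[i]]
    if (is.null(s)) return(NA_character_)
    if (length(setdiff(s, "None of the above")) > 0) "housing need"
    else "no housing need"
  }))

  it <- items_of("perceived_stress")
  pss <- per_person(function(i)
    strict(aligned(truth$perceived_stress, it, i), sum))
  emit("df_pss_total", pss)
  emit("df_pss_category", per_person_chr(function(i) {
    t <- pss[i]
    if (is.na(t)) NA_character_
    else if (t <= 13) "low stress"
    else if (t <= 26) "moderate stress"
    else "high stress"
  }))

  it <- items_of("spiritual_experiences")
  emit("df_dses", per_person(function(i)
    strict(aligned(truth$spiritual_experiences, it, i), sum)))
  emit("df_dses_nonbelief_zero", per_person(function(i)
    strict(aligned(truth$spiritual_experiences_alt, it, i), sum)))

  it <- items_of("religious_attendance")
  emit("df_religious_attendance", per_person_chr(function(i) {
    v <- truth$religious_attendance[[it$question_code[1]]][i]
    if (is.na(v)) NA_character_ else as.character(v)
  }))

  it <- items_of("english_proficiency")
  gate <- truth$english_proficiency[[it$question_code[1]]]
  sub <- truth$english_proficiency[[it$question_code[2]]]
  emit("df_english_binary", per_person_chr(function(i) {
    if (is.na(gate[i])) NA_character_ else as.character(gate[i])
  }))
  emit("df_english_ordinal", per_person_chr(function(i) {
    if (is.na(gate[i]) || gate[i] != "Yes" || is.na(sub[i])) NA_character_
    else as.character(sub[i])
  }))
  emit("df_english_collapsed", per_person_chr(function(i) {
    if (is.na(gate[i]) || gate[i] != "Yes" || is.na(sub[i]))
      return(NA_character_)
    if (sub[i] %in% c("Very well", "Well")) "proficient"
    else if (sub[i] %in% c("Not well", "Not at all")) "not proficient"
    else "unknown"
  }))

  out[registry$scoring$option_id]
}
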