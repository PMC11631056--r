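# Naive reference scorer. Computes every scoring option straight from the
# wide ground-truth values with plain base-R arithmetic, independently of the
# production engine's registry dispatch — generate_cohort() uses it to label
# its cohorts, and the test suite uses the same brute-force logic to check
# score_all() end to end.

#' Score ground-truth wide value tables with the naive reference scorer
#'
#' @param mats Named list of wide value tibbles as returned in
#'   `generate_cohort()$truth_matrices`.
#' @param registry An `sdoh_registry` (consulted only for item polarity and
#'   the chronicity map, which are configuration, not code).
#' @return Named list of 30 score tibbles (`person_id`, `score`,
#'   `option_id`).
#' @keywords internal
#' @export
naive_scores <- function(mats, registry = sdoh_registry()) {
  pid <- mats[[1]]$person_id
  out <- list()
  emit <- function(option_id, score) {
    out[[option_id]] <<- tibble::tibble(person_id = pid, score = score,
                                        option_id = option_id)
  }
  vals <- function(con, idx = NULL, reversed_ok = TRUE) {
    items <- .construct_items(registry, con)
    if (!is.null(idx)) items <- items[items$item_index %in% idx, ]
    V <- vapply(items$question_code,
                function(qc) as.numeric(mats[[con]][[qc]]),
                numeric(length(pid)))
    if (!is.matrix(V)) V <- matrix(V, nrow = length(pid),
                                   dimnames = list(NULL, items$question_code))
    if (reversed_ok) {
      for (k in seq_len(nrow(items))) {
        if (items$polarity[k] == "reversed") {
          V[, k] <- items$scale_min[k] + items$scale_max[k] - V[, k]
        }
      }
    }
    V
  }
  labs <- function(con, idx) {
    items <- .construct_items(registry, con)
    mats[[con]][[items$question_code[items$item_index == idx]]]
  }

  emit("df_cohesion", rowMeans(vals("cohesion")))
  D <- vals("disorder")
  emit("df_disorder", rowMeans(D))
  emit("df_disorder_physical", rowMeans(D[, 1:6, drop = FALSE]))
  emit("df_disorder_social", rowMeans(D[, 7:13, drop = FALSE]))
  E <- vals("environment", idx = 2:8)
  emit("df_panes_total", rowSums(E))
  dens <- labs("environment", 1)
  Eraw <- vals("environment", idx = 2:6, reversed_ok = FALSE)
  emit("df_nei", ifelse(is.na(dens), NA_real_,
                        as.numeric(dens != .density_low)) +
         rowSums(Eraw >= 3))
  emit("df_crime_safety", rowSums(E[, 6:7, drop = FALSE]))
  S <- vals("social_support")
  emit("df_support", 100 * (rowMeans(S) - 1) / 4)
  emit("df_support_instrumental", 100 * (rowMeans(S[, 1:4, drop = FALSE]) - 1) / 4)
  emit("df_support_emotional", 100 * (rowMeans(S[, 5:8, drop = FALSE]) - 1) / 4)
  emit("df_loneliness", rowSums(vals("loneliness")))
  EDS <- vals("everyday_discrimination", idx = 1:9)
  emit("df_edd_situation", rowSums(EDS > 1))
  emit("df_edd_frequency", rowSums(EDS))
  cm <- registry$chronicity_map
  emit("df_edd_chronicity",
       rowSums(matrix(cm[as.character(EDS)], nrow = length(pid))))
  emit("df_edd_reason", as.character(labs("everyday_discrimination", 10)))
  DMS <- vals("healthcare_discrimination")
  any_dms <- rowSums(DMS > 1)
  emit("df_dms_never_ever",
       ifelse(is.na(any_dms), NA_character_,
              ifelse(any_dms > 0, "any", "none")))
  emit("df_dms_count", rowSums(DMS > 1))
  emit("df_dms_sum", rowSums(DMS))
  emit("df_dms_average", rowMeans(DMS))
  f1 <- labs("food_insecurity", 1); f2 <- labs("food_insecurity", 2)
  risky <- c("Often true", "Sometimes true")
  emit("df_food_insecurity",
       ifelse(is.na(f1) | is.na(f2), NA_character_,
              ifelse(f1 %in% risky | f2 %in% risky, "at risk", "not at risk")))
  moves <- as.numeric(mats$housing_insecurity[[2]])
  emit("df_housing_insecurity",
       ifelse(is.na(moves), NA_character_,
              ifelse(moves >= 2, "at risk", "not at risk")))
  sets <- mats$housing_quality[[2]]
  emit("df_housing_quality", vapply(sets, function(s) {
    if (is.null(s)) return(NA_character_)
    if (length(setdiff(s, "None of the above"))) "housing need"
    else "no housing need"
  }, character(1)))
  pss_total <- rowSums(vals("perceived_stress"))
  emit("df_pss_total", pss_total)
  emit("df_pss_category",
       ifelse(is.na(pss_total), NA_character_,
              ifelse(pss_total <= 13, "low stress",
                     ifelse(pss_total <= 26, "moderate stress", "high stress"))))
  emit("df_dses", rowSums(vals("spiritual_experiences")))
  DA <- vapply(.construct_items(registry, "spiritual_experiences")$question_code,
               function(qc) as.numeric(mats$spiritual_experiences_alt[[qc]]),
               numeric(length(pid)))
  if (!is.matrix(DA)) DA <- matrix(DA, nrow = length(pid))
  emit("df_dses_nonbelief_zero", rowSums(DA))
  emit("df_religious_attendance", as.character(labs("religious_attendance", 1)))
  gate <- labs("english_proficiency", 1)
  sub <- labs("english_proficiency", 2)
  emit("df_english_binary", as.character(gate))
  ord <- ifelse(is.na(gate) | gate != "Yes", NA_character_, sub)
  emit("df_english_ordinal", ord)
  emit("df_english_collapsed",
       ifelse(is.na(ord), NA_character_,
              ifelse(ord %in% c("Very well", "Well"), "proficient",
                     ifelse(ord %in% c("Not well", "Not at all"),
                            "not proficient", "unknown"))))

  out[registry$scoring$option_id]
}
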