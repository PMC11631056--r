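# Hand-built worked-case participants: the annualized-discrimination worked
# example, all-maximum/all-minimum responders (range endpoints), one-skip
# responders per construct, and perceived-stress responders sitting exactly
# on the category cut points.

# answer codes for one full pass over the survey at a named response level
.level_codes <- function(registry, level = c("max", "min", "mid")) {
  level <- match.arg(level)
  items <- registry$items
  rows <- list()
  add <- function(question_code, answer_code) {
    rows[[length(rows) + 1L]] <<-
      tibble::tibble(question_code = question_code, answer_code = answer_code)
  }
  cat_pick <- list(
    DENSITY = c(max = "DENSITY_4", min = "DENSITY_1", mid = "DENSITY_2"),
    FOOD3 = c(max = "FOOD3_1", min = "FOOD3_3", mid = "FOOD3_3"),
    ATTEND = c(max = "ATTEND_5", min = "ATTEND_1", mid = "ATTEND_3"),
    YESNO = c(max = "YESNO_1", min = "YESNO_2", mid = "YESNO_1"),
    PROFICIENCY = c(max = "PROFICIENCY_1", min = "PROFICIENCY_4",
                    mid = "PROFICIENCY_2"),
    EDS_REASON = c(max = "EDS_REASON_3", min = "EDS_REASON_13",
                   mid = "EDS_REASON_4")
  )
  gate_code <- NULL
  for (k in seq_len(nrow(items))) {
    item <- items[k, ]
    if (item$item_kind == "checklist") {
      codes <- switch(level,
                      max = sprintf("HOUSING_CHECK_%d", 1:7),
                      min = "HOUSING_CHECK_8",
                      mid = "HOUSING_CHECK_2")
      for (code in codes) add(item$question_code, code)
      next
    }
    if (item$item_kind == "count") {
      add(item$question_code,
          switch(level, max = "MOVES_5", min = "MOVES_0", mid = "MOVES_1"))
      next
    }
    if (item$item_kind == "categorical") {
      code <- cat_pick[[item$vocab]][[level]]
      if (!is.na(item$branching_parent)) {
        # emit the proficiency sub-item only when the gate answer triggers it
        if (!identical(gate_code, "YESNO_1")) next
      }
      if (item$vocab == "YESNO") gate_code <- code
      add(item$question_code, code)
      next
    }
    # Likert: pick the raw value whose polarity-aligned value is extreme,
    # so the all-max responder hits every score's printed maximum
    opts <- registry$options[registry$options$question_code == item$question_code &
                               registry$options$role == "scale_value", ]
    v <- switch(level,
      max = if (item$polarity == "reversed") min(opts$value) else max(opts$value),
      min = if (item$polarity == "reversed") max(opts$value) else min(opts$value),
      mid = sort(opts$value)[ceiling(nrow(opts) / 2)]
    )
    code <- opts$answer_code[opts$value == v][1]
    # the all-minimum spiritual-experiences responder uses the survey-added
    # nonbelief option where one exists (standard coding 1, alternative 0)
    if (level == "min" && item$vocab == "DSES6_NB") code <- "DSES_NO_BELIEF"
    add(item$question_code, code)
  }
  dplyr::bind_rows(rows)
}

.codes_to_rows <- function(registry, person_id, codes) {
  m <- match(paste(codes$question_code, codes$answer_code),
             paste(registry$options$question_code, registry$options$answer_code))
  tibble::tibble(
    person_id = person_id,
    question_code = codes$question_code,
    answer_code = codes$answer_code,
    answer_text = registry$options$answer_text[m],
    answer_numeric = registry$options$value[m],
    survey_datetime = "2022-06-30T12:00:00Z"
  )
}

#' Worked-case fixture participants
#'
#' Returns a small hand-built response table containing, among others:
#' \itemize{
#'   \item `eds_worked` — answers "Almost every day" on one everyday
#'     discrimination item and "Never" on the other eight (annualized
#'     chronicity total 260).
#'   \item `resp_max` / `resp_min` — all-maximum and all-minimum responders
#'     whose scores land on every printed range endpoint.
#'   \item `skip_<construct>` — mid-level responders who skip exactly one
#'     item of one construct (scored `NA` there, everywhere else intact).
#'   \item `pss_13`, `pss_14`, `pss_26`, `pss_27` — perceived-stress totals
#'     exactly at the low/moderate/high category cut points.
#' }
#'
#' @param registry An `sdoh_registry`.
#' @return A long response tibble.
#' @examples
#' calc_eds(fixture_participants(), "chronicity")
#' @export
fixture_participants <- function(registry = sdoh_registry()) {
  chunks <- list()

  eds_items <- .construct_items(registry, "everyday_discrimination")
  eds_codes <- tibble::tibble(
    question_code = eds_items$question_code[1:9],
    answer_code = c("EDS6_6", rep("EDS6_1", 8))
  )
  chunks$eds_worked <- .codes_to_rows(registry, "eds_worked", eds_codes)

  chunks$resp_max <- .codes_to_rows(registry, "resp_max",
                                    .level_codes(registry, "max"))
  chunks$resp_min <- .codes_to_rows(registry, "resp_min",
                                    .level_codes(registry, "min"))

  mid <- .level_codes(registry, "mid")
  for (con in unique(registry$items$construct)) {
    first_q <- .construct_items(registry, con)$question_code[1]
    codes <- mid
    codes$answer_code[codes$question_code == first_q] <- "PMI_SKIP"
    codes <- codes[!duplicated(codes$question_code) |
                     codes$question_code != first_q, ]
    # skipping a gate item also suppresses its branching child's row
    kids <- registry$items$question_code[
      !is.na(registry$items$branching_parent) &
        registry$items$branching_parent == first_q]
    codes <- codes[!codes$question_code %in% kids, ]
    pid <- paste0("skip_", con)
    chunks[[pid]] <- .codes_to_rows(registry, pid, codes)
  }

  # raw perceived-stress answers whose polarity-aligned totals hit the cut
  # points exactly (items 4, 5, 7, 8 are reverse-scored on the 0-4 scale)
  pss_items <- .construct_items(registry, "perceived_stress")
  pss_targets <- list(
    pss_13 = c(2, 2, 2, 2, 1, 1, 1, 1, 1, 0),
    pss_14 = c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1),
    pss_26 = c(3, 3, 3, 3, 3, 3, 2, 2, 2, 2),
    pss_27 = c(3, 3, 3, 3, 3, 3, 3, 2, 2, 2)
  )
  for (pid in names(pss_targets)) {
    aligned <- pss_targets[[pid]]
    raw <- ifelse(pss_items$polarity == "reversed", 4 - aligned, aligned)
    codes <- tibble::tibble(question_code = pss_items$question_code,
                            answer_code = sprintf("PSS5_%d", raw))
    chunks[[pid]] <- .codes_to_rows(registry, pid, codes)
  }

  dplyr::bind_rows(chunks)
}
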