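# Worked examples per construct, the complete-case/NA contract, and the
# cross-variant consistency properties.

test_that("cohesion mean score and complete-case handling", {
  resp <- dplyr::bind_rows(
    construct_responses("p1", "cohesion", c(5, 4, 3, 2)),
    construct_responses("p2", "cohesion", c(5, 5, 5, 5)),
    construct_responses("p3", "cohesion", c(1, 1, 1, 1)),
    make_responses("p4", "SDOH_COHESION_1", "PMI_SKIP"),
    make_responses("p5", "SDOH_EDS_1", "EDS6_1")  # no cohesion rows
  )
  s <- calc_cohesion(resp)
  expect_identical(nrow(s), 5L)
  expect_identical(score_of(list(df_cohesion = s), "df_cohesion", "p1"), 3.5)
  expect_identical(s$score[s$person_id == "p2"], 5)
  expect_identical(s$score[s$person_id == "p3"], 1)
  expect_true(is.na(s$score[s$person_id == "p4"]))
  expect_true(is.na(s$score[s$person_id == "p5"]))
})

test_that("disorder means align order items with disorder items", {
  # polarity-aligned physical values (1,2,3,4,1,1): items 5-6 are
  # order-oriented, so their raw responses are 5 - aligned value
  raw <- c(1, 2, 3, 4, 4, 4)
  resp <- construct_responses("p1", "disorder", raw)
  s <- calc_disorder(resp, "physical")
  expect_identical(s$score, 2)   # 12 / 6
  # total needs all 13 items
  expect_true(is.na(calc_disorder(resp, "total")$score))
  full <- construct_responses("p2", "disorder",
                              c(4, 4, 4, 4, 1, 1, 4, 4, 4, 4, 4, 1, 1))
  expect_identical(calc_disorder(full, "total")$score, 4)
  expect_identical(calc_disorder(full, "social")$score, 4)
})

test_that("environment scores: PANES total, NEI, crime safety", {
  env_items <- sprintf("SDOH_PANES_%d", 2:8)
  resp <- make_responses("p1", env_items,
                         c(rep("AGREE4_4", 5), "AGREE4_1", "AGREE4_1"))
  expect_identical(calc_panes_total(resp)$score, 28)  # crime reversed to 4

  resp_lo <- make_responses("p2", env_items, rep("AGREE4_1", 5) |>
                              c("AGREE4_4", "AGREE4_4"))
  expect_identical(calc_panes_total(resp_lo)$score, 7)

  # density "detached single family" scores 0, five favorable items score 1
  nei <- make_responses("p3", sprintf("SDOH_PANES_%d", 1:6),
                        c("DENSITY_1", rep("AGREE4_3", 5)))
  expect_identical(calc_nei(nei)$score, 5)
  nei2 <- make_responses("p4", sprintf("SDOH_PANES_%d", 1:6),
                         c("DENSITY_3", rep("AGREE4_2", 5)))
  expect_identical(calc_nei(nei2)$score, 1)

  crime <- make_responses("p5", c("SDOH_PANES_7", "SDOH_PANES_8"),
                          c("AGREE4_4", "AGREE4_4"))
  expect_identical(calc_crime_safety(crime)$score, 2)
  crime2 <- make_responses("p6", c("SDOH_PANES_7", "SDOH_PANES_8"),
                           c("AGREE4_1", "AGREE4_1"))
  expect_identical(calc_crime_safety(crime2)$score, 8)
  one <- make_responses("p7", "SDOH_PANES_7", "AGREE4_1")
  expect_true(is.na(calc_crime_safety(one)$score))
})

test_that("social support transforms the item average to 0-100", {
  resp <- construct_responses("p1", "social_support", rep(3, 8))
  expect_identical(calc_social_support(resp)$score, 50)
  expect_identical(calc_social_support(resp, "instrumental")$score, 50)
  hi <- construct_responses("p2", "social_support", rep(5, 8))
  expect_identical(calc_social_support(hi)$score, 100)
  lo <- construct_responses("p3", "social_support", rep(1, 8))
  expect_identical(calc_social_support(lo)$score, 0)
  # subscale membership: items 1-4 instrumental, 5-8 emotional
  mixed <- construct_responses("p4", "social_support",
                               c(5, 5, 5, 5, 1, 1, 1, 1))
  expect_identical(calc_social_support(mixed, "instrumental")$score, 100)
  expect_identical(calc_social_support(mixed, "emotional")$score, 0)
})

test_that("loneliness total reverses its two positively worded items", {
  resp <- construct_responses("p1", "loneliness", rep(2, 8))
  expect_identical(calc_loneliness(resp)$score, 18)  # 6*2 + 2*3
  hi <- construct_responses("p2", "loneliness", c(4, 4, 1, 4, 4, 1, 4, 4))
  expect_identical(calc_loneliness(hi)$score, 32)
  lo <- construct_responses("p3", "loneliness", c(1, 1, 4, 1, 1, 4, 1, 1))
  expect_identical(calc_loneliness(lo)$score, 8)
})

test_that("everyday discrimination: situation, frequency, chronicity", {
  worked <- fixture_participants()
  chron <- calc_eds(worked, "chronicity")
  expect_identical(chron$score[chron$person_id == "eds_worked"], 260)
  expect_identical(chron$score[chron$person_id == "resp_max"], 2340)

  sit <- calc_eds(worked, "situation")
  expect_identical(sit$score[sit$person_id == "eds_worked"], 1)
  expect_identical(sit$score[sit$person_id == "resp_min"], 0)
  freq <- calc_eds(worked, "frequency")
  expect_identical(freq$score[freq$person_id == "resp_min"], 9)
  expect_identical(freq$score[freq$person_id == "resp_max"], 54)

  # strictly more frequent category -> strictly larger chronicity
  base <- construct_responses("p", "everyday_discrimination", rep(3, 9))
  up <- construct_responses("p", "everyday_discrimination", c(4, rep(3, 8)))
  expect_gt(calc_eds(up, "chronicity")$score,
            calc_eds(base, "chronicity")$score)
})

test_that("EDS variants agree on who reports no discrimination", {
  co <- generate_cohort(cohort_spec(n = 60, seed = 5, missingness = 0.05,
                                    skip_rate = 0.05))
  s <- score_all(co$responses, options = c("df_edd_situation",
                                           "df_edd_frequency",
                                           "df_edd_chronicity"))
  sit <- s$df_edd_situation$score
  freq <- s$df_edd_frequency$score
  chron <- s$df_edd_chronicity$score
  expect_identical(is.na(sit), is.na(freq))
  expect_identical(is.na(sit), is.na(chron))
  ok <- !is.na(sit)
  expect_identical(sit[ok] == 0, freq[ok] == 9)
  expect_identical(sit[ok] == 0, chron[ok] == 0)
})

test_that("main-reason follow-up relabels or stays NA", {
  resp <- dplyr::bind_rows(
    make_responses("p1", "SDOH_EDS_10", "EDS_REASON_3"),
    make_responses("p2", "SDOH_EDS_10", "PMI_SKIP"),
    make_responses("p3", "SDOH_EDS_1", "EDS6_1")
  )
  s <- relabel_eds_reason(resp)
  expect_identical(s$score[s$person_id == "p1"], "Your race")
  expect_true(is.na(s$score[s$person_id == "p2"]))
  expect_true(is.na(s$score[s$person_id == "p3"]))
})

test_that("medical-settings discrimination variants and their consistency", {
  never <- construct_responses("p1", "healthcare_discrimination", rep(1, 7))
  expect_identical(calc_dms(never, "never_ever")$score, "none")
  expect_identical(calc_dms(never, "count")$score, 0)
  expect_identical(calc_dms(never, "sum")$score, 7)
  expect_identical(calc_dms(never, "average")$score, 1)

  always <- construct_responses("p2", "healthcare_discrimination", rep(5, 7))
  expect_identical(calc_dms(always, "count")$score, 7)
  expect_identical(calc_dms(always, "sum")$score, 35)
  expect_identical(calc_dms(always, "average")$score, 5)

  one <- construct_responses("p3", "healthcare_discrimination",
                             c(1, 1, 1, 2, 1, 1, 1))
  expect_identical(calc_dms(one, "never_ever")$score, "any")
  expect_identical(calc_dms(one, "count")$score, 1)

  co <- generate_cohort(cohort_spec(n = 60, seed = 6))
  s <- score_all(co$responses, options = c("df_dms_never_ever", "df_dms_count",
                                           "df_dms_sum", "df_dms_average"))
  ok <- !is.na(s$df_dms_count$score)
  expect_identical(s$df_dms_count$score[ok] == 0,
                   s$df_dms_never_ever$score[ok] == "none")
  expect_identical(s$df_dms_count$score[ok] == 0, s$df_dms_sum$score[ok] == 7)
  expect_identical(s$df_dms_count$score[ok] == 0,
                   s$df_dms_average$score[ok] == 1)
})

test_that("food insecurity screen follows the either-item rule", {
  often_never <- make_responses("p1", c("SDOH_FOOD_1", "SDOH_FOOD_2"),
                                c("FOOD3_1", "FOOD3_3"))
  expect_identical(calc_food_insecurity(often_never)$score, "at risk")
  never_never <- make_responses("p2", c("SDOH_FOOD_1", "SDOH_FOOD_2"),
                                c("FOOD3_3", "FOOD3_3"))
  expect_identical(calc_food_insecurity(never_never)$score, "not at risk")
  # one item missing -> NA even though the answered item already screens in
  half <- make_responses("p3", "SDOH_FOOD_1", "FOOD3_2")
  expect_true(is.na(calc_food_insecurity(half)$score))
})

test_that("housing insecurity flags two or more moves", {
  for (case in list(list("MOVES_0", "not at risk"), list("MOVES_1", "not at risk"),
                    list("MOVES_2", "at risk"), list("MOVES_5", "at risk"))) {
    resp <- make_responses("p", "SDOH_MOVES_1", case[[1]])
    expect_identical(calc_housing_insecurity(resp)$score, case[[2]])
  }
})

test_that("housing quality needs any problem except 'none of the above'", {
  mold <- make_responses("p1", "SDOH_HOUSING_1", "HOUSING_CHECK_2")
  expect_identical(calc_housing_quality(mold)$score, "housing need")
  none <- make_responses("p2", "SDOH_HOUSING_1", "HOUSING_CHECK_8")
  expect_identical(calc_housing_quality(none)$score, "no housing need")
  conflict <- make_responses("p3", rep("SDOH_HOUSING_1", 2),
                             c("HOUSING_CHECK_8", "HOUSING_CHECK_7"))
  expect_warning(s <- calc_housing_quality(conflict), "problems win")
  expect_identical(s$score, "housing need")
  absent <- make_responses("p4", "SDOH_EDS_1", "EDS6_1")
  expect_true(is.na(calc_housing_quality(absent)$score))
})

test_that("perceived stress totals and categories at the cut points", {
  fix <- fixture_participants()
  tot <- calc_pss(fix, "total")
  cat <- calc_pss(fix, "category")
  get <- function(tab, p) tab$score[tab$person_id == p]
  expect_identical(get(tot, "pss_13"), 13)
  expect_identical(get(tot, "pss_14"), 14)
  expect_identical(get(tot, "pss_26"), 26)
  expect_identical(get(tot, "pss_27"), 27)
  expect_identical(get(cat, "pss_13"), "low stress")
  expect_identical(get(cat, "pss_14"), "moderate stress")
  expect_identical(get(cat, "pss_26"), "moderate stress")
  expect_identical(get(cat, "pss_27"), "high stress")
  expect_identical(get(tot, "resp_max"), 40)
  expect_identical(get(tot, "resp_min"), 0)
})

test_that("spiritual experiences: standard vs nonbelief-zero coding", {
  hi <- construct_responses("p1", "spiritual_experiences", rep(6, 6))
  expect_identical(calc_dses(hi)$score, 36)
  expect_identical(calc_dses(hi, "nonbelief_zero")$score, 36)

  nb_items <- REG$items$question_code[REG$items$construct == "spiritual_experiences"]
  codes <- c("DSES_NO_BELIEF", "DSES_NOT_RELIGIOUS", "DSES6_1",
             "DSES_NO_BELIEF", "DSES_NOT_RELIGIOUS", "DSES6_1")
  nb <- make_responses("p2", nb_items, codes)
  expect_identical(calc_dses(nb, "standard")$score, 6)
  expect_identical(calc_dses(nb, "nonbelief_zero")$score, 2)
})

test_that("religious attendance keeps 'I am not religious' separate", {
  resp <- dplyr::bind_rows(
    make_responses("p1", "SDOH_ATTEND_1", "ATTEND_5"),
    make_responses("p2", "SDOH_ATTEND_1", "ATTEND_6"),
    make_responses("p3", "SDOH_ATTEND_1", "PMI_SKIP")
  )
  s <- calc_religious_attendance(resp)
  expect_identical(s$score[s$person_id == "p1"], "More than once a week")
  expect_identical(s$score[s$person_id == "p2"], "I am not religious")
  expect_true(is.na(s$score[s$person_id == "p3"]))
})

test_that("English proficiency options dichotomize, order, and collapse", {
  resp <- dplyr::bind_rows(
    make_responses("very_well", c("SDOH_ENGLISH_1", "SDOH_ENGLISH_2"),
                   c("YESNO_1", "PROFICIENCY_1")),
    make_responses("not_at_all", c("SDOH_ENGLISH_1", "SDOH_ENGLISH_2"),
                   c("YESNO_1", "PROFICIENCY_4")),
    make_responses("dont_know", c("SDOH_ENGLISH_1", "SDOH_ENGLISH_2"),
                   c("YESNO_1", "PMI_DONT_KNOW")),
    make_responses("english_only", "SDOH_ENGLISH_1", "YESNO_2")
  )
  bin <- calc_english_proficiency(resp, "binary_other_language")
  expect_identical(bin$score[bin$person_id == "very_well"], "Yes")
  expect_identical(bin$score[bin$person_id == "english_only"], "No")

  ord <- calc_english_proficiency(resp, "ordinal")
  expect_identical(ord$score[ord$person_id == "dont_know"], "Don't know")
  expect_true(is.na(ord$score[ord$person_id == "english_only"]))

  col <- calc_english_proficiency(resp, "collapsed")
  get <- function(p) col$score[col$person_id == p]
  expect_identical(get("very_well"), "proficient")
  expect_identical(get("not_at_all"), "not proficient")
  expect_identical(get("dont_know"), "unknown")
  expect_true(is.na(get("english_only")))
})

test_that("score_option enforces construct, value-map and polarity contracts", {
  m <- map_answers(construct_responses("p", "cohesion", c(3, 3, 3, 3)),
                   "cohesion")
  expect_error(score_option(m, "df_loneliness"), "construct")
  lon <- map_answers(construct_responses("p", "loneliness", rep(2, 8)),
                     "loneliness")
  expect_error(score_option(lon, "df_loneliness"), "apply_polarity")
  dses <- map_answers(construct_responses("p", "spiritual_experiences",
                                          rep(2, 6)),
                      "spiritual_experiences")
  expect_error(score_option(dses, "df_dses_nonbelief_zero"), "value_map")
})

test_that("score_all keeps every participant in all 30 tables", {
  # all-yes gates so branching introduces no not-applicable NA
  spec <- cohort_spec(n = 10, seed = 2, missingness = 0, skip_rate = 0,
                      response_weights = list(SDOH_ENGLISH_1 = c(1, 0)))
  co <- generate_cohort(spec)
  s <- score_all(co$responses)
  expect_identical(length(s), 30L)
  for (tab in s) {
    expect_identical(nrow(tab), 10L)
    expect_false(anyNA(tab$score))
  }

  # a participant who skips everything is NA in all 30 tables but present
  all_q <- REG$items$question_code
  skipper <- make_responses("ghost", all_q, rep("PMI_SKIP", length(all_q)))
  s2 <- score_all(dplyr::bind_rows(co$responses, skipper))
  for (tab in s2) {
    expect_identical(nrow(tab), 11L)
    expect_true(is.na(tab$score[tab$person_id == "ghost"]))
  }
})

test_that("raising a polarity-aligned item never lowers a sum/mean score", {
  base_vals <- c(2, 2, 2, 2, 2, 2, 2, 2)
  for (item in 1:8) {
    vals <- base_vals
    vals[item] <- 3
    # raw value up on a reversed item lowers the aligned value, so align first
    items <- REG$items[REG$items$construct == "loneliness", ]
    raw <- ifelse(items$polarity == "reversed", 5 - vals, vals)
    raw_base <- ifelse(items$polarity == "reversed", 5 - base_vals, base_vals)
    up <- calc_loneliness(construct_responses("p", "loneliness", raw))$score
    ref <- calc_loneliness(construct_responses("p", "loneliness", raw_base))$score
    expect_gte(up, ref)
  }
})
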