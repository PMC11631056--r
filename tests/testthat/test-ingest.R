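test_that("read_responses parses the export dialect and flags bad files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,question_concept_id,question,answer_concept_id,answer,survey_datetime",
    "p1,SDOH_COHESION_1,q,AGREE5_5,Strongly agree,2022-01-01T00:00:00Z",
    "p1,SDOH_COHESION_2,q,AGREE5_4,Agree,2022-01-01T00:00:00Z",
    "p2,SDOH_COHESION_1,q,PMI_SKIP,Skip,2022-01-01T00:00:00Z"
  ), path)
  tab <- read_responses(path)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$question_code[1], "SDOH_COHESION_1")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("question_concept_id,answer_concept_id,answer,question",
               "SDOH_COHESION_1,AGREE5_5,x,q"), bad)
  expect_error(read_responses(bad), "person_id")
})

test_that("duplicate non-checklist rows resolve last-wins with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,question_concept_id,question,answer_concept_id,answer,survey_datetime",
    "p1,SDOH_COHESION_1,q,AGREE5_2,Disagree,2022-01-01T00:00:00Z",
    "p1,SDOH_COHESION_1,q,AGREE5_5,Strongly agree,2022-03-01T00:00:00Z"
  ), path)
  expect_warning(tab <- read_responses(path), "last-wins")
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$answer_code, "AGREE5_5")

  # checklist items legitimately carry several rows per person
  check <- make_responses("p1", rep("SDOH_HOUSING_1", 2),
                          c("HOUSING_CHECK_1", "HOUSING_CHECK_2"))
  expect_no_warning(dedupe_out <- sdohscores:::dedupe_responses(check, REG))
  expect_identical(nrow(dedupe_out), 2L)
})

test_that("map_answers maps codes to values and marks missingness", {
  resp <- dplyr::bind_rows(
    construct_responses("p1", "cohesion", c(5, 4, 3, 2)),
    make_responses("p2", "SDOH_COHESION_1", "PMI_SKIP"),
    make_responses("p3", "SDOH_EDS_1", "EDS6_2")   # no cohesion rows at all
  )
  m <- map_answers(resp, "cohesion")
  expect_setequal(m$person_id, c("p1", "p2", "p3"))
  expect_identical(m$SDOH_COHESION_1[m$person_id == "p1"], 5)
  expect_true(is.na(m$SDOH_COHESION_1[m$person_id == "p2"]))
  expect_true(all(is.na(unlist(m[m$person_id == "p3", 2:5]))))
  expect_identical(m$.complete, c(TRUE, FALSE, FALSE))

  bad <- make_responses("p9", "SDOH_COHESION_1", "AGREE5_1")
  bad$answer_code <- "XYZ"
  expect_error(map_answers(bad, "cohesion"), "unknown answer code 'XYZ'")
})

test_that("branching sub-item is not-applicable unless the gate says yes", {
  resp <- dplyr::bind_rows(
    make_responses("yes_person", c("SDOH_ENGLISH_1", "SDOH_ENGLISH_2"),
                   c("YESNO_1", "PROFICIENCY_1")),
    make_responses("no_person", "SDOH_ENGLISH_1", "YESNO_2")
  )
  m <- map_answers(resp, "english_proficiency")
  expect_identical(m$SDOH_ENGLISH_2[m$person_id == "yes_person"], "Very well")
  expect_true(is.na(m$SDOH_ENGLISH_2[m$person_id == "no_person"]))

  stray <- dplyr::bind_rows(
    make_responses("p", c("SDOH_ENGLISH_1", "SDOH_ENGLISH_2"),
                   c("YESNO_2", "PROFICIENCY_1"))
  )
  expect_warning(m2 <- map_answers(stray, "english_proficiency"),
                 "without triggering gate")
  expect_true(is.na(m2$SDOH_ENGLISH_2))
})

test_that("reverse_score swaps endpoints, fixes midpoints, rejects out-of-bounds", {
  expect_identical(reverse_score(1, 1, 4), 4)
  expect_identical(reverse_score(4, 1, 4), 1)
  expect_identical(reverse_score(2, 0, 4), 2)
  expect_true(is.na(reverse_score(NA_real_, 1, 4)))
  expect_error(reverse_score(5, 1, 4), "out of scale bounds")
})

test_that("apply_polarity reverses marked items and is an involution", {
  resp <- construct_responses("p1", "loneliness", c(4, 4, 4, 4, 4, 4, 4, 4))
  m <- map_answers(resp, "loneliness")
  rev <- apply_polarity(m)
  expect_identical(rev$SDOH_LONELINESS_3, 1)   # "I am an outgoing person"
  expect_identical(rev$SDOH_LONELINESS_1, 4)   # normal item unchanged
  twice <- apply_polarity(rev)
  expect_equal(as.data.frame(twice)[names(m)], as.data.frame(m)[names(m)])

  # normal-polarity constructs pass through unchanged
  coh <- map_answers(construct_responses("p1", "cohesion", c(5, 4, 3, 2)),
                     "cohesion")
  expect_equal(as.data.frame(apply_polarity(coh)), as.data.frame(coh),
               ignore_attr = TRUE)
})

test_that("mapped values stay within scale bounds or are missing", {
  co <- generate_cohort(cohort_spec(n = 40, seed = 11, missingness = 0.1,
                                    skip_rate = 0.1))
  for (con in c("cohesion", "disorder", "loneliness", "perceived_stress",
                "spiritual_experiences")) {
    items <- REG$items[REG$items$construct == con, ]
    m <- map_answers(co$responses, con)
    for (k in seq_len(nrow(items))) {
      v <- m[[items$question_code[k]]]
      v <- v[!is.na(v)]
      expect_true(all(v >= items$scale_min[k] & v <= items$scale_max[k]))
    }
  }
})
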