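# Built-in registry describing the Social Determinants of Health Survey:
# 14 constructs, 80 items, their response vocabularies, item polarities, and
# the catalogue of 30 scoring options. All question/answer codes are
# deterministic placeholders (the Researcher Workbench's real concept IDs are
# controlled-access); sdoh_registry(config) rebinds them from a user config.

# --- response vocabularies ---------------------------------------------------

.vocab_scale <- function(id, labels, values) {
  tibble::tibble(
    answer_code = sprintf("%s_%d", id, values),
    answer_text = labels,
    value = as.numeric(values),
    value_alt = as.numeric(values),
    label = NA_character_,
    role = "scale_value"
  )
}

.vocab_category <- function(id, labels) {
  tibble::tibble(
    answer_code = sprintf("%s_%d", id, seq_along(labels)),
    answer_text = labels,
    value = NA_real_,
    value_alt = NA_real_,
    label = labels,
    role = "special_category"
  )
}

# Standard programme-wide non-response codes. `retain` turns the
# dont_know/prefer_not codes into kept category labels (English proficiency).
.vocab_skips <- function(retain = FALSE) {
  out <- tibble::tibble(
    answer_code = c("PMI_SKIP", "PMI_DONT_KNOW", "PMI_PREFER_NOT_TO_ANSWER"),
    answer_text = c("Skip", "Don't know", "Prefer not to answer"),
    value = NA_real_,
    value_alt = NA_real_,
    label = NA_character_,
    role = c("skip", "dont_know", "prefer_not")
  )
  if (retain) {
    out$label[out$role %in% c("dont_know", "prefer_not")] <-
      c("Don't know", "Prefer not to answer")
  }
  out
}

.agree5 <- c("Strongly disagree", "Disagree", "Neither agree nor disagree",
             "Agree", "Strongly agree")
.agree4 <- c("Strongly disagree", "Disagree", "Agree", "Strongly agree")
.uls4 <- c("Never", "Rarely", "Sometimes", "Always")
.time5 <- c("None of the time", "A little of the time", "Some of the time",
            "Most of the time", "All of the time")
.eds6 <- c("Never", "Less than once a year", "A few times a year",
           "A few times a month", "At least once a week", "Almost every day")
.dms5 <- c("Never", "Rarely", "Sometimes", "Most of the time", "Always")
.pss5 <- c("Never", "Almost never", "Sometimes", "Fairly often", "Very often")
.dses6 <- c("Never or almost never", "Once in a while", "Some days",
            "Most days", "Every day", "Many times a day")
.food3 <- c("Often true", "Sometimes true", "Never true")
.density_levels <- c(
  "Detached single-family housing",
  "Townhouses, row houses, apartments, or condos of 2-3 stories",
  "Mix of single-family residences and townhouses, row houses, apartments, or condos",
  "Apartments or condos of 4-12 stories",
  "Apartments or condos of more than 12 stories"
)
.housing_quality_choices <- c(
  "Pests such as bugs, ants, or mice", "Mold", "Lead paint or pipes",
  "Lack of heat", "Oven or stove not working",
  "Smoke detectors missing or not working", "Water leaks", "None of the above"
)
.attendance_levels <- c(
  "Never (or almost never)", "Less than once per month", "1-3 times per month",
  "Once a week", "More than once a week", "I am not religious"
)
.reason_levels <- c(
  "Your ancestry or national origins", "Your gender", "Your race", "Your age",
  "Your religion", "Your height", "Your weight",
  "Some other aspect of your physical appearance", "Your sexual orientation",
  "Your education or income level", "A physical disability",
  "Your shade of skin color", "Other"
)
.proficiency_levels <- c("Very well", "Well", "Not well", "Not at all",
                         "Prefer not to answer", "Don't know")

# Detached single-family housing marks low residential density (NEI value 0).
.density_low <- .density_levels[1]

.default_chronicity_map <- c(
  "1" = 0, "2" = 0.5, "3" = 3, "4" = 36, "5" = 52, "6" = 260
)

# --- items -------------------------------------------------------------------

.item_row <- function(construct, item_index, question_code, question_text,
                      item_kind = "likert", scale_min = NA_real_,
                      scale_max = NA_real_, polarity = "normal",
                      subscale = NA_character_, vocab = NA_character_,
                      counted = TRUE, branching_parent = NA_character_,
                      branching_trigger = NA_character_) {
  tibble::tibble(
    construct = construct, item_index = as.integer(item_index),
    question_code = question_code, question_text = question_text,
    item_kind = item_kind, scale_min = as.numeric(scale_min),
    scale_max = as.numeric(scale_max), polarity = polarity,
    subscale = subscale, vocab = vocab, counted = counted,
    branching_parent = branching_parent, branching_trigger = branching_trigger
  )
}

.default_items <- function() {
  li <- list()
  add <- function(...) li[[length(li) + 1L]] <<- .item_row(...)

  # Neighborhood cohesion: 4 positively stated 5-point items, mean score 1-5.
  coh <- c(
    "People around here are willing to help their neighbors",
    "People in my neighborhood generally get along with each other",
    "People in my neighborhood can be trusted",
    "People in my neighborhood share the same values"
  )
  for (i in 1:4) {
    add("cohesion", i, sprintf("SDOH_COHESION_%d", i), coh[i],
        scale_min = 1, scale_max = 5, vocab = "AGREE5")
  }

  # Neighborhood disorder: 13 of the 15 Perceived Neighborhood Disorder Scale
  # items (police-protection and trust items dropped). Order-oriented items
  # are reverse-scored so higher always means disorder. 6 physical / 7 social.
  dis <- list(
    list("There is a lot of graffiti in my neighborhood", "physical", "normal"),
    list("My neighborhood is noisy", "physical", "normal"),
    list("Vandalism is common in my neighborhood", "physical", "normal"),
    list("There are a lot of abandoned buildings in my neighborhood", "physical", "normal"),
    list("My neighborhood is clean", "physical", "reversed"),
    list("People in my neighborhood take good care of their houses and apartments", "physical", "reversed"),
    list("There are too many people hanging around on the streets near my home", "social", "normal"),
    list("There is a lot of crime in my neighborhood", "social", "normal"),
    list("There is too much drug use in my neighborhood", "social", "normal"),
    list("There is too much alcohol use in my neighborhood", "social", "normal"),
    list("I'm always having trouble with my neighbors", "social", "normal"),
    list("My neighborhood is safe", "social", "reversed"),
    list("People in my neighborhood watch out for each other", "social", "reversed")
  )
  for (i in seq_along(dis)) {
    add("disorder", i, sprintf("SDOH_DISORDER_%d", i), dis[[i]][[1]],
        scale_min = 1, scale_max = 4, polarity = dis[[i]][[3]],
        subscale = dis[[i]][[2]], vocab = "AGREE4")
  }

  # Neighborhood environment (PANES): categorical residential-density item,
  # five 4-point built-environment items, two negatively worded crime items.
  add("environment", 1, "SDOH_PANES_1",
      "What is the main type of housing in your neighborhood?",
      item_kind = "categorical", subscale = "density", vocab = "DENSITY")
  env <- c(
    "Many shops, stores, markets, or other places to buy things I need are within easy walking distance of my home",
    "It is within a 10-15 minute walk to a transit stop from my home",
    "There are sidewalks on most of the streets in my neighborhood",
    "There are facilities to bicycle in or near my neighborhood",
    "My neighborhood has several free or low-cost recreation facilities"
  )
  for (i in seq_along(env)) {
    add("environment", i + 1L, sprintf("SDOH_PANES_%d", i + 1L), env[i],
        scale_min = 1, scale_max = 4, subscale = "core", vocab = "AGREE4_PANES")
  }
  add("environment", 7, "SDOH_PANES_7",
      "The crime rate in my neighborhood makes it unsafe to go on walks at night",
      scale_min = 1, scale_max = 4, polarity = "reversed", subscale = "crime",
      vocab = "AGREE4_PANES")
  add("environment", 8, "SDOH_PANES_8",
      "The crime rate in my neighborhood makes it unsafe to go on walks during the day",
      scale_min = 1, scale_max = 4, polarity = "reversed", subscale = "crime",
      vocab = "AGREE4_PANES")

  # Social support (mMOS-SS): 4 instrumental + 4 emotional 5-point items.
  sup <- list(
    list("Someone to help you if you were confined to bed", "instrumental"),
    list("Someone to take you to the doctor if you needed it", "instrumental"),
    list("Someone to prepare your meals if you were unable to do it yourself", "instrumental"),
    list("Someone to help with daily chores if you were sick", "instrumental"),
    list("Someone to have a good time with", "emotional"),
    list("Someone to turn to for suggestions about how to deal with a personal problem", "emotional"),
    list("Someone who understands your problems", "emotional"),
    list("Someone to love and make you feel wanted", "emotional")
  )
  for (i in seq_along(sup)) {
    add("social_support", i, sprintf("SDOH_SUPPORT_%d", i), sup[[i]][[1]],
        scale_min = 1, scale_max = 5, subscale = sup[[i]][[2]], vocab = "TIME5")
  }

  # Loneliness (ULS-8): 2 positively worded items reverse-scored.
  lon <- list(
    list("I lack companionship", "normal"),
    list("There is no one I can turn to", "normal"),
    list("I am an outgoing person", "reversed"),
    list("I feel left out", "normal"),
    list("I feel isolated from others", "normal"),
    list("I can find companionship when I want it", "reversed"),
    list("I am unhappy being so withdrawn", "normal"),
    list("People are around me but not with me", "normal")
  )
  for (i in seq_along(lon)) {
    add("loneliness", i, sprintf("SDOH_LONELINESS_%d", i), lon[[i]][[1]],
        scale_min = 1, scale_max = 4, polarity = lon[[i]][[2]], vocab = "ULS4")
  }

  # Everyday discrimination (EDS): 9 frequency items + main-reason follow-up.
  eds <- c(
    "You are treated with less courtesy than other people are",
    "You are treated with less respect than other people are",
    "You receive poorer service than other people at restaurants or stores",
    "People act as if they think you are not smart",
    "People act as if they are afraid of you",
    "People act as if they think you are dishonest",
    "People act as if they're better than you are",
    "You are called names or insulted",
    "You are threatened or harassed"
  )
  for (i in seq_along(eds)) {
    add("everyday_discrimination", i, sprintf("SDOH_EDS_%d", i), eds[i],
        scale_min = 1, scale_max = 6, vocab = "EDS6")
  }
  add("everyday_discrimination", 10, "SDOH_EDS_10",
      "What do you think is the main reason for these experiences?",
      item_kind = "categorical", subscale = "reason", vocab = "EDS_REASON")

  # Discrimination in medical settings (DMS): 7 5-point frequency items.
  dms <- c(
    "You are treated with less courtesy than other people",
    "You are treated with less respect than other people",
    "You receive poorer service than others",
    "A doctor or nurse acts as if he or she thinks you are not smart",
    "A doctor or nurse acts as if he or she is afraid of you",
    "A doctor or nurse acts as if he or she is better than you",
    "You feel like a doctor or nurse is not listening to what you were saying"
  )
  for (i in seq_along(dms)) {
    add("healthcare_discrimination", i, sprintf("SDOH_DMS_%d", i), dms[i],
        scale_min = 1, scale_max = 5, vocab = "DMS5")
  }

  # Food insecurity (Hunger Vital Sign): 2 categorical items.
  add("food_insecurity", 1, "SDOH_FOOD_1",
      "Within the past 12 months, we worried whether our food would run out before we got money to buy more",
      item_kind = "categorical", vocab = "FOOD3")
  add("food_insecurity", 2, "SDOH_FOOD_2",
      "Within the past 12 months, the food we bought just didn't last and we didn't have money to get more",
      item_kind = "categorical", vocab = "FOOD3")

  # Housing insecurity/instability: move count in the last 12 months.
  add("housing_insecurity", 1, "SDOH_MOVES_1",
      "In the last 12 months, how many times have you or your family moved from one home to another?",
      item_kind = "count", scale_min = 0, scale_max = 10, vocab = "MOVES")

  # Housing quality: select-all-that-apply problem checklist.
  add("housing_quality", 1, "SDOH_HOUSING_1",
      "Think about the place you live. Do you have problems with any of the following?",
      item_kind = "checklist", vocab = "HOUSING_CHECK")

  # Perceived stress (PSS-10): 0-4 items; the 4 positively worded items are
  # reverse-scored, bound by their text rather than position.
  pss <- list(
    list("In the last month, how often have you been upset because of something that happened unexpectedly?", "normal"),
    list("In the last month, how often have you felt that you were unable to control the important things in your life?", "normal"),
    list("In the last month, how often have you felt nervous and stressed?", "normal"),
    list("In the last month, how often have you felt confident about your ability to handle your personal problems?", "reversed"),
    list("In the last month, how often have you felt that things were going your way?", "reversed"),
    list("In the last month, how often have you found that you could not cope with all the things that you had to do?", "normal"),
    list("In the last month, how often have you been able to control irritations in your life?", "reversed"),
    list("In the last month, how often have you felt that you were on top of things?", "reversed"),
    list("In the last month, how often have you been angered because of things that were outside of your control?", "normal"),
    list("In the last month, how often have you felt difficulties were piling up so high that you could not overcome them?", "normal")
  )
  for (i in seq_along(pss)) {
    add("perceived_stress", i, sprintf("SDOH_PSS_%d", i), pss[[i]][[1]],
        scale_min = 0, scale_max = 4, polarity = pss[[i]][[2]], vocab = "PSS5")
  }

  # Daily spiritual experiences (DSES short form): items 1, 2, 4, 5 carry the
  # two survey-added nonbelief response options.
  dses <- list(
    list("I feel God's (or a higher power's) presence", "DSES6_NB"),
    list("I find strength and comfort in my religion", "DSES6_NB"),
    list("I feel deep inner peace or harmony", "DSES6"),
    list("I desire to be closer to God (or a higher power) or in union with the divine", "DSES6_NB"),
    list("I feel God's (or a higher power's) love for me directly or through others", "DSES6_NB"),
    list("I am spiritually touched by the beauty of creation", "DSES6")
  )
  for (i in seq_along(dses)) {
    add("spiritual_experiences", i, sprintf("SDOH_DSES_%d", i),
        dses[[i]][[1]], scale_min = 1, scale_max = 6, vocab = dses[[i]][[2]])
  }

  # Religious service attendance: single item, "I am not religious" kept as a
  # separate category.
  add("religious_attendance", 1, "SDOH_ATTEND_1",
      "How often do you go to religious meetings or services?",
      item_kind = "categorical", vocab = "ATTEND")

  # English proficiency: gate item plus branching proficiency sub-item shown
  # only when the gate response is "Yes". The sub-item does not count toward
  # the survey's 80 items.
  add("english_proficiency", 1, "SDOH_ENGLISH_1",
      "Do you speak a language other than English at home?",
      item_kind = "categorical", vocab = "YESNO")
  add("english_proficiency", 2, "SDOH_ENGLISH_2",
      "Since you speak a language other than English at home, we are interested in your own opinion of how well you speak English. Would you say you speak English...",
      item_kind = "categorical", vocab = "PROFICIENCY", counted = FALSE,
      branching_parent = "SDOH_ENGLISH_1", branching_trigger = "Yes")

  dplyr::bind_rows(li)
}

# --- answer options ----------------------------------------------------------

.vocab_table <- function(vocab) {
  switch(vocab,
    AGREE5 = dplyr::bind_rows(.vocab_scale("AGREE5", .agree5, 1:5), .vocab_skips()),
    AGREE4 = dplyr::bind_rows(.vocab_scale("AGREE4", .agree4, 1:4), .vocab_skips()),
    # PANES items add "does not apply" and "don't know/not sure" responses,
    # both treated as missing (such items drop the participant's total under
    # the complete-case contract).
    AGREE4_PANES = dplyr::bind_rows(
      .vocab_scale("AGREE4", .agree4, 1:4),
      tibble::tibble(
        answer_code = c("PANES_NOT_APPLY", "PANES_DK_NOT_SURE"),
        answer_text = c("Does not apply to my neighborhood", "Don't know/not sure"),
        value = NA_real_, value_alt = NA_real_, label = NA_character_,
        role = c("special_category", "dont_know")
      ),
      .vocab_skips()
    ),
    ULS4 = dplyr::bind_rows(.vocab_scale("ULS4", .uls4, 1:4), .vocab_skips()),
    TIME5 = dplyr::bind_rows(.vocab_scale("TIME5", .time5, 1:5), .vocab_skips()),
    EDS6 = dplyr::bind_rows(.vocab_scale("EDS6", .eds6, 1:6), .vocab_skips()),
    DENSITY = dplyr::bind_rows(.vocab_category("DENSITY", .density_levels), .vocab_skips()),
    EDS_REASON = dplyr::bind_rows(.vocab_category("EDS_REASON", .reason_levels), .vocab_skips()),
    DMS5 = dplyr::bind_rows(.vocab_scale("DMS5", .dms5, 1:5), .vocab_skips()),
    FOOD3 = dplyr::bind_rows(.vocab_category("FOOD3", .food3), .vocab_skips()),
    MOVES = dplyr::bind_rows(.vocab_scale("MOVES", as.character(0:10), 0:10), .vocab_skips()),
    HOUSING_CHECK = dplyr::bind_rows(
      tibble::tibble(
        answer_code = sprintf("HOUSING_CHECK_%d", seq_along(.housing_quality_choices)),
        answer_text = .housing_quality_choices,
        value = NA_real_, value_alt = NA_real_,
        label = .housing_quality_choices, role = "checklist_choice"
      ),
      .vocab_skips()
    ),
    PSS5 = dplyr::bind_rows(.vocab_scale("PSS5", .pss5, 0:4), .vocab_skips()),
    # Standard coding values the added nonbelief options at 1 ("never or
    # almost never"); the alternative coding sets them to 0 (value_alt).
    DSES6 = dplyr::bind_rows(.vocab_scale("DSES6", .dses6, 1:6), .vocab_skips()),
    DSES6_NB = dplyr::bind_rows(
      .vocab_scale("DSES6", .dses6, 1:6),
      tibble::tibble(
        answer_code = c("DSES_NO_BELIEF", "DSES_NOT_RELIGIOUS"),
        answer_text = c("I do not believe in God (or a higher power)",
                        "I am not religious"),
        value = 1, value_alt = 0, label = NA_character_,
        role = "special_category"
      ),
      .vocab_skips()
    ),
    ATTEND = dplyr::bind_rows(.vocab_category("ATTEND", .attendance_levels), .vocab_skips()),
    YESNO = dplyr::bind_rows(.vocab_category("YESNO", c("Yes", "No")), .vocab_skips()),
    PROFICIENCY = dplyr::bind_rows(
      .vocab_category("PROFICIENCY", .proficiency_levels[1:4]),
      .vocab_skips(retain = TRUE)
    ),
    stop("unknown response vocabulary: ", vocab, call. = FALSE)
  )
}

.default_options <- function(items) {
  purrr::map2_dfr(items$question_code, items$vocab, function(qc, vocab) {
    opts <- .vocab_table(vocab)
    opts$question_code <- qc
    dplyr::relocate(opts, "question_code")
  })
}

# --- scoring options ---------------------------------------------------------

.default_scoring <- function() {
  sc <- function(option_id, construct, reducer, output_kind,
                 items, range_min = NA_real_, range_max = NA_real_,
                 labels = NULL, value_map = "standard") {
    tibble::tibble(
      option_id = option_id, construct = construct, reducer = reducer,
      output_kind = output_kind, items = list(as.integer(items)),
      range_min = as.numeric(range_min), range_max = as.numeric(range_max),
      labels = list(labels %||% character()), value_map = value_map
    )
  }
  dplyr::bind_rows(
    sc("df_cohesion", "cohesion", "mean", "numeric", 1:4, 1, 5),
    sc("df_disorder", "disorder", "mean", "numeric", 1:13, 1, 4),
    sc("df_disorder_physical", "disorder", "mean", "numeric", 1:6, 1, 4),
    sc("df_disorder_social", "disorder", "mean", "numeric", 7:13, 1, 4),
    sc("df_panes_total", "environment", "sum", "numeric", 2:8, 7, 28),
    sc("df_nei", "environment", "nei", "numeric", 1:6, 0, 6),
    sc("df_crime_safety", "environment", "sum", "numeric", 7:8, 2, 8),
    sc("df_support", "social_support", "transformed_mean_0_100", "numeric", 1:8, 0, 100),
    sc("df_support_instrumental", "social_support", "transformed_mean_0_100", "numeric", 1:4, 0, 100),
    sc("df_support_emotional", "social_support", "transformed_mean_0_100", "numeric", 5:8, 0, 100),
    sc("df_loneliness", "loneliness", "sum", "numeric", 1:8, 8, 32),
    sc("df_edd_situation", "everyday_discrimination", "situation", "numeric", 1:9, 0, 9),
    sc("df_edd_frequency", "everyday_discrimination", "sum", "numeric", 1:9, 9, 54),
    sc("df_edd_chronicity", "everyday_discrimination", "chronicity", "numeric", 1:9, 0, 2340),
    sc("df_edd_reason", "everyday_discrimination", "relabel", "categorical", 10,
       labels = .reason_levels),
    sc("df_dms_never_ever", "healthcare_discrimination", "never_ever", "binary", 1:7,
       labels = c("none", "any")),
    sc("df_dms_count", "healthcare_discrimination", "count", "numeric", 1:7, 0, 7),
    sc("df_dms_sum", "healthcare_discrimination", "sum", "numeric", 1:7, 7, 35),
    sc("df_dms_average", "healthcare_discrimination", "mean", "numeric", 1:7, 1, 5),
    sc("df_food_insecurity", "food_insecurity", "screen_any", "binary", 1:2,
       labels = c("not at risk", "at risk")),
    sc("df_housing_insecurity", "housing_insecurity", "threshold_moves", "binary", 1,
       labels = c("not at risk", "at risk")),
    sc("df_housing_quality", "housing_quality", "checklist_need", "binary", 1,
       labels = c("no housing need", "housing need")),
    sc("df_pss_total", "perceived_stress", "sum", "numeric", 1:10, 0, 40),
    sc("df_pss_category", "perceived_stress", "pss_category", "categorical", 1:10,
       labels = c("low stress", "moderate stress", "high stress")),
    sc("df_dses", "spiritual_experiences", "sum", "numeric", 1:6, 6, 36),
    sc("df_dses_nonbelief_zero", "spiritual_experiences", "sum", "numeric", 1:6, 2, 36,
       value_map = "nonbelief_zero"),
    sc("df_religious_attendance", "religious_attendance", "relabel", "categorical", 1,
       labels = .attendance_levels),
    sc("df_english_binary", "english_proficiency", "relabel", "binary", 1,
       labels = c("Yes", "No")),
    sc("df_english_ordinal", "english_proficiency", "english_ordinal", "categorical", 1:2,
       labels = .proficiency_levels),
    sc("df_english_collapsed", "english_proficiency", "english_collapsed", "categorical", 1:2,
       labels = c("proficient", "not proficient", "unknown"))
  )
}

# Item counts printed for the survey, used by validate_registry().
.expected_item_counts <- c(
  cohesion = 4L, disorder = 13L, environment = 8L, social_support = 8L,
  loneliness = 8L, everyday_discrimination = 10L,
  healthcare_discrimination = 7L, food_insecurity = 2L,
  housing_insecurity = 1L, housing_quality = 1L, perceived_stress = 10L,
  spiritual_experiences = 6L, religious_attendance = 1L,
  english_proficiency = 1L
)
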