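# Shared test scaffolding: a registry built once, and a tiny constructor for
# hand-written response rows.

REG <- sdoh_registry()

# long response rows from (person, question_code, answer_code) triples
make_responses <- function(person_id, question_code, answer_code) {
  m <- match(paste(question_code, answer_code),
             paste(REG$options$question_code, REG$options$answer_code))
  tibble::tibble(
    person_id = person_id,
    question_code = question_code,
    answer_code = answer_code,
    answer_text = REG$options$answer_text[m],
    answer_numeric = REG$options$value[m],
    survey_datetime = "2022-06-30T12:00:00Z"
  )
}

# one person answering a whole construct with the given scale values
construct_responses <- function(person_id, construct, values) {
  items <- REG$items[REG$items$construct == construct, ]
  items <- items[order(items$item_index), ][seq_along(values), ]
  codes <- vapply(seq_along(values), function(k) {
    opts <- REG$options[REG$options$question_code == items$question_code[k] &
                          REG$options$role == "scale_value", ]
    opts$answer_code[match(values[k], opts$value)]
  }, character(1))
  make_responses(person_id, items$question_code, codes)
}

score_of <- function(scores, option_id, person) {
  tab <- scores[[option_id]]
  tab$score[tab$person_id == person]
}
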