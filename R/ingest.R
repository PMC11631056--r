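#' Read a long-format survey response export
#'
#' Reads the CSV dialect exported for the survey concept set: one row per
#' participant-item (several rows for the select-all-that-apply housing
#' checklist). Required columns: `person_id`, `question_concept_id`,
#' `question`, `answer_concept_id`, `answer`. Optional: `answer_numeric`,
#' `survey_datetime`.
#'
#' Duplicate `(person, question)` rows on non-checklist items are resolved
#' last-wins (by `survey_datetime` when present, then file order) with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @param registry Registry used to recognise checklist items (default:
#'   built-in).
#' @return A tibble with columns `person_id`, `question_code`, `answer_code`,
#'   `answer_text`, `answer_numeric`, `survey_datetime`.
#' @export
read_responses <- function(path, registry = sdoh_registry()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("person_id", "question_concept_id", "question",
                "answer_concept_id", "answer")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    person_id = raw$person_id,
    question_code = raw$question_concept_id,
    answer_code = raw$answer_concept_id,
    answer_text = raw$answer,
    answer_numeric = if ("answer_numeric" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$answer_numeric))
    } else NA_real_,
    survey_datetime = if ("survey_datetime" %in% names(raw)) {
      raw$survey_datetime
    } else NA_character_
  )
  dedupe_responses(out, registry)
}

# Last-wins dedup of non-checklist (person, question) rows; ISO timestamps
# order lexically, ties broken by row order.
dedupe_responses <- function(responses, registry) {
  checklist <- registry$items$question_code[registry$items$item_kind == "checklist"]
  is_check <- responses$question_code %in% checklist
  dup <- duplicated(responses[, c("person_id", "question_code")]) & !is_check
  if (!any(dup)) return(responses)
  warning(sum(dup), " duplicate response row(s) resolved last-wins",
          call. = FALSE)
  plain <- responses[!is_check, ] |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$person_id, .data$question_code,
                   !is.na(.data$survey_datetime), .data$survey_datetime,
                   .data$.row) |>
    dplyr::group_by(.data$person_id, .data$question_code) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
  dplyr::bind_rows(plain, responses[is_check, ])
}

#' Reverse-score a value on a bounded scale
#'
#' Maps `value` to `scale_min + scale_max - value`, the standard Likert
#' reversal so all items of a scale point the same direction before
#' aggregation. `NA` passes through.
#'
#' @param value Numeric vector.
#' @param scale_min,scale_max Scale bounds.
#' @return Numeric vector of the same length.
#' @examples
#' reverse_score(c(1, 4), 1, 4) # 4 1
#' @export
reverse_score <- function(value, scale_min, scale_max) {
  ok <- is.na(value) | (value >= scale_min & value <= scale_max)
  if (!all(ok)) {
    stop("value out of scale bounds [", scale_min, ", ", scale_max, "]: ",
         paste(value[!ok], collapse = ", "), call. = FALSE)
  }
  scale_min + scale_max - value
}

#' Pivot responses to a per-construct participant-by-item matrix
#'
#' Implements the relabelling steps of scoring: select the construct's items,
#' map each `answer_code` through the registry's response options, and pivot
#' to one column per item (named by question code). Skip, don't-know and
#' prefer-not responses become `NA` unless the construct retains them as
#' categories; participants with no row for an item get `NA`; branching
#' sub-items are `NA` (not applicable) when the gate response does not match
#' the trigger. Every participant present anywhere in `responses` appears as
#' a row — missingness is marked, never filtered.
#'
#' @param responses A response tibble from [read_responses()] (or built in
#'   code with the same columns).
#' @param construct Construct name, e.g. `"cohesion"`; see
#'   `sdoh_registry()$items`.
#' @param registry An `sdoh_registry`.
#' @param value_map `"standard"` or `"nonbelief_zero"`; only meaningful for
#'   `spiritual_experiences`, where the survey-added nonbelief options are
#'   valued 1 or 0 respectively.
#' @return A tibble (class `sdoh_item_matrix`) with `person_id`, one column
#'   per item, and a logical `.complete` flag (all counted items non-missing,
#'   branching children excluded). Numeric items give numeric columns,
#'   categorical items character label columns, checklist items list-columns
#'   of endorsed choices.
#' @export
map_answers <- function(responses, construct, registry = sdoh_registry(),
                        value_map = c("standard", "nonbelief_zero")) {
  value_map <- match.arg(value_map)
  items <- .construct_items(registry, construct)
  persons <- unique(responses$person_id)
  rows <- responses[responses$question_code %in% items$question_code, ]

  opts <- registry$options
  cols <- stats::setNames(vector("list", nrow(items)), items$question_code)
  for (k in seq_len(nrow(items))) {
    item <- items[k, ]
    irow <- rows[rows$question_code == item$question_code, ]
    iopts <- opts[opts$question_code == item$question_code, ]
    unknown <- setdiff(irow$answer_code, iopts$answer_code)
    if (length(unknown) && item$item_kind == "count") {
      # closed vocabulary plus a numeric fallback for count entry
      fallback <- irow$answer_code %in% unknown & !is.na(irow$answer_numeric)
      unknown <- setdiff(unique(irow$answer_code[!fallback]), iopts$answer_code)
    }
    if (length(unknown)) {
      bad <- irow[irow$answer_code %in% unknown, ][1, ]
      stop(sprintf("unknown answer code '%s' for person %s on item %s",
                   bad$answer_code, bad$person_id, item$question_code),
           call. = FALSE)
    }
    if (item$item_kind == "checklist") {
      sets <- lapply(persons, function(p) {
        prow <- irow[irow$person_id == p, ]
        if (!nrow(prow)) return(NULL)
        lab <- iopts$label[match(prow$answer_code, iopts$answer_code)]
        lab <- lab[!is.na(lab)]
        if (!length(lab)) NULL else unique(lab)
      })
      cols[[item$question_code]] <- sets
    } else if (item$item_kind %in% c("likert", "count")) {
      vals <- if (value_map == "nonbelief_zero") iopts$value_alt else iopts$value
      v <- vals[match(irow$answer_code, iopts$answer_code)]
      num_fallback <- is.na(match(irow$answer_code, iopts$answer_code))
      v[num_fallback] <- irow$answer_numeric[num_fallback]
      cols[[item$question_code]] <- v[match(persons, irow$person_id)]
    } else {
      lab <- iopts$label[match(irow$answer_code, iopts$answer_code)]
      cols[[item$question_code]] <- lab[match(persons, irow$person_id)]
    }
  }
  mat <- tibble::tibble(person_id = persons, !!!cols)

  # branching children: not-applicable unless gate matches the trigger
  kids <- items[!is.na(items$branching_parent), ]
  for (k in seq_len(nrow(kids))) {
    kid <- kids[k, ]
    gate <- mat[[kid$branching_parent]]
    if (is.null(gate)) next
    off <- is.na(gate) | gate != kid$branching_trigger
    stray <- off & !is.na(mat[[kid$question_code]])
    if (any(stray)) {
      warning(sum(stray), " sub-item response(s) for item ", kid$question_code,
              " without triggering gate response; ignored", call. = FALSE)
    }
    mat[[kid$question_code]][off] <- NA
  }

  required <- items$question_code[items$counted]
  miss <- vapply(required, function(qc) {
    col <- mat[[qc]]
    if (is.list(col)) vapply(col, is.null, logical(1)) else is.na(col)
  }, logical(length(persons)))
  if (length(persons) == 1L) miss <- matrix(miss, nrow = 1L)
  mat$.complete <- if (length(persons)) rowSums(miss) == 0L else logical()

  structure(mat,
            class = c("sdoh_item_matrix", class(tibble::tibble()))) |>
    .set_matrix_attrs(construct = construct, value_map = value_map,
                      polarity_applied = FALSE)
}

.set_matrix_attrs <- function(mat, construct, value_map, polarity_applied) {
  attr(mat, "construct") <- construct
  attr(mat, "value_map") <- value_map
  attr(mat, "polarity_applied") <- polarity_applied
  mat
}

#' Apply item polarity (reverse scoring) to an item matrix
#'
#' Reverse-scores every item the registry marks `reversed` (e.g. the 2
#' positively worded loneliness items, the 4 positively worded stress items,
#' order-oriented disorder items, the 2 crime-safety items). Other columns
#' and missing values pass through unchanged. Applying the transformation
#' twice restores the original matrix.
#'
#' @param matrix An `sdoh_item_matrix` from [map_answers()].
#' @param registry An `sdoh_registry`.
#' @return The matrix with reversed items transformed; attribute
#'   `polarity_applied` toggled.
#' @export
apply_polarity <- function(matrix, registry = sdoh_registry()) {
  construct <- attr(matrix, "construct")
  items <- .construct_items(registry, construct)
  rev_items <- items[items$polarity == "reversed", ]
  for (k in seq_len(nrow(rev_items))) {
    it <- rev_items[k, ]
    matrix[[it$question_code]] <-
      reverse_score(matrix[[it$question_code]], it$scale_min, it$scale_max)
  }
  attr(matrix, "polarity_applied") <- !isTRUE(attr(matrix, "polarity_applied"))
  matrix
}
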