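# Synthetic cohorts in the survey's long export format, with ground truth.
# The generator draws item values first (the ground truth), scores them with
# a deliberately naive scorer that works straight off the drawn wide values,
# and only then serializes to the long response table — so the production
# pipeline (parse, relabel, pivot, reverse, reduce) can be checked end to end
# against known answers.

#' Describe a synthetic cohort
#'
#' @param n Number of participants.
#' @param seed Integer seed; the same spec and seed always reproduce the same
#'   cohort byte for byte.
#' @param missingness Per-item probability that a participant has no row at
#'   all for an item.
#' @param skip_rate Per-item probability that an answered item is the "Skip"
#'   code (a non-response that still produces a row).
#' @param response_weights Optional named list: question code to numeric
#'   weights over that item's scale/category options (registry order).
#'   Defaults: centre-peaked weights for Likert items, uniform for
#'   categorical items, geometric decay for the move count.
#' @param branching_consistent If `TRUE` (default) the English-proficiency
#'   sub-item row is emitted only for participants whose gate response is
#'   "Yes"; `FALSE` emits stray sub-item rows to exercise the ingest warning.
#' @return A `sdoh_cohort_spec` list.
#' @export
cohort_spec <- function(n, seed = 1L, missingness = 0.02, skip_rate = 0.02,
                        response_weights = NULL, branching_consistent = TRUE) {
  stopifnot(n >= 0, missingness >= 0, missingness <= 1,
            skip_rate >= 0, skip_rate <= 1)
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         missingness = missingness, skip_rate = skip_rate,
         response_weights = response_weights,
         branching_consistent = isTRUE(branching_consistent)),
    class = "sdoh_cohort_spec"
  )
}

.default_weights <- function(item, iopts) {
  k <- nrow(iopts)
  if (item$item_kind == "likert") {
    centre <- (k + 1) / 2
    w <- 1 / (1 + abs(seq_len(k) - centre))
  } else if (item$item_kind == "count") {
    w <- 0.55^(seq_len(k) - 1)
  } else {
    w <- rep(1, k)
  }
  w / sum(w)
}

# options a generated answer may take: anything carrying a value or a
# retained label (this keeps the English-proficiency "Don't know"/"Prefer not
# to answer" categories in play and excludes pure non-response codes)
.candidate_options <- function(registry, question_code) {
  opts <- registry$options[registry$options$question_code == question_code, ]
  opts[!is.na(opts$value) | !is.na(opts$label), ]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws responses for all 80 survey items (plus the branching
#' English-proficiency sub-item) under the spec's missingness and skip rates.
#' All random draws happen once, in canonical registry order, so a given
#' `(spec, seed)` reproduces the identical cohort regardless of how the
#' result is consumed.
#'
#' @param spec A [cohort_spec()].
#' @param registry An `sdoh_registry`.
#' @param truth_scores Compute the ground-truth score tables (default `TRUE`;
#'   turn off for very large cohorts where only the responses and drawn
#'   values are needed).
#' @return A list:
#' \describe{
#'   \item{`responses`}{long response tibble in the ingest CSV dialect.}
#'   \item{`truth_matrices`}{named list of wide participant-by-item tibbles of
#'     the drawn values (one per construct; `spiritual_experiences_alt`
#'     carries the nonbelief-zero coding).}
#'   \item{`truth_scores`}{named list of 30 ground-truth score tibbles,
#'     computed by the generator's naive scorer.}
#' }
#' @export
generate_cohort <- function(spec, registry = sdoh_registry(),
                            truth_scores = TRUE) {
  stopifnot(inherits(spec, "sdoh_cohort_spec"))
  n <- spec$n
  persons <- if (n > 0) sprintf("P%06d", seq_len(n)) else character()
  items <- dplyr::arrange(registry$items, match(.data$construct,
                                               unique(registry$items$construct)),
                          .data$item_index)
  set.seed(spec$seed)

  drawn <- vector("list", nrow(items))   # per item: answer codes or NA
  names(drawn) <- items$question_code
  checklist_sets <- NULL
  for (k in seq_len(nrow(items))) {
    item <- items[k, ]
    if (item$item_kind == "checklist") {
      # independent endorsement of each problem; none endorsed -> the
      # "None of the above" choice
      probs <- matrix(stats::runif(n * 7), nrow = max(n, 0))
      u_miss <- stats::runif(n)
      u_skip <- stats::runif(n)
      sets <- lapply(seq_len(n), function(i) {
        if (u_miss[i] < spec$missingness) return(NULL)
        if (u_skip[i] < spec$skip_rate) return("PMI_SKIP")
        endorsed <- which(probs[i, ] < 0.15)
        if (!length(endorsed)) "HOUSING_CHECK_8"
        else sprintf("HOUSING_CHECK_%d", endorsed)
      })
      checklist_sets <- sets
      drawn[[item$question_code]] <- NA   # handled separately
      next
    }
    cand <- .candidate_options(registry, item$question_code)
    w <- spec$response_weights[[item$question_code]] %||%
      .default_weights(item, cand)
    stopifnot(length(w) == nrow(cand), all(w >= 0))
    u_miss <- stats::runif(n)
    u_skip <- stats::runif(n)
    idx <- sample.int(nrow(cand), n, replace = TRUE, prob = w)
    code <- cand$answer_code[idx]
    code[u_skip < spec$skip_rate] <- "PMI_SKIP"
    code[u_miss < spec$missingness] <- NA_character_
    drawn[[item$question_code]] <- code
  }

  # enforce branching: the proficiency sub-item exists only for gate == Yes
  gate_yes <- drawn[["SDOH_ENGLISH_1"]] == "YESNO_1"
  gate_yes[is.na(gate_yes)] <- FALSE

  truth_matrices <- .truth_matrices(registry, persons, drawn, checklist_sets,
                                    gate_yes)
  responses <- .assemble_long(registry, items, persons, drawn, checklist_sets,
                              gate_yes, spec$branching_consistent)
  out <- list(responses = responses, truth_matrices = truth_matrices,
              spec = spec)
  if (truth_scores) {
    out$truth_scores <- naive_scores(truth_matrices, registry)
  }
  out
}

# wide ground-truth value tibbles, same shape map_answers() produces
.truth_matrices <- function(registry, persons, drawn, checklist_sets,
                            gate_yes) {
  opts <- registry$options
  constructs <- unique(registry$items$construct)
  mats <- list()
  for (con in c(constructs, "spiritual_experiences_alt")) {
    base_con <- sub("_alt$", "", con)
    use_alt <- endsWith(con, "_alt")
    items <- .construct_items(registry, base_con)
    cols <- list(person_id = persons)
    for (k in seq_len(nrow(items))) {
      item <- items[k, ]
      if (item$item_kind == "checklist") {
        cols[[item$question_code]] <- lapply(checklist_sets, function(s) {
          if (is.null(s) || identical(s, "PMI_SKIP")) return(NULL)
          iopts <- opts[opts$question_code == item$question_code, ]
          iopts$label[match(s, iopts$answer_code)]
        })
        next
      }
      code <- drawn[[item$question_code]]
      iopts <- opts[opts$question_code == item$question_code, ]
      m <- match(code, iopts$answer_code)
      if (item$item_kind %in% c("likert", "count")) {
        v <- if (use_alt) iopts$value_alt[m] else iopts$value[m]
      } else {
        v <- iopts$label[m]
      }
      if (!is.na(item$branching_parent)) v[!gate_yes] <- NA
      cols[[item$question_code]] <- v
    }
    mats[[con]] <- tibble::as_tibble(cols)
  }
  mats
}

.assemble_long <- function(registry, items, persons, drawn, checklist_sets,
                           gate_yes, branching_consistent) {
  opts <- registry$options
  chunks <- list()
  for (k in seq_len(nrow(items))) {
    item <- items[k, ]
    iopts <- opts[opts$question_code == item$question_code, ]
    if (item$item_kind == "checklist") {
      idx <- rep(seq_along(persons), lengths(checklist_sets))
      codes <- unlist(checklist_sets)
      if (!length(idx)) next
      m <- match(codes, iopts$answer_code)
      chunks[[length(chunks) + 1L]] <- tibble::tibble(
        person_id = persons[idx],
        question_code = item$question_code,
        answer_code = codes,
        answer_text = iopts$answer_text[m],
        answer_numeric = NA_real_,
        .item_order = k
      )
      next
    }
    code <- drawn[[item$question_code]]
    keep <- !is.na(code)
    if (!is.na(item$branching_parent) && branching_consistent) {
      keep <- keep & gate_yes
    }
    if (!any(keep)) next
    m <- match(code[keep], iopts$answer_code)
    chunks[[length(chunks) + 1L]] <- tibble::tibble(
      person_id = persons[keep],
      question_code = item$question_code,
      answer_code = code[keep],
      answer_text = iopts$answer_text[m],
      answer_numeric = iopts$value[m],
      .item_order = k
    )
  }
  if (!length(chunks)) {
    return(tibble::tibble(person_id = character(), question_code = character(),
                          answer_code = character(), answer_text = character(),
                          answer_numeric = numeric(),
                          survey_datetime = character()))
  }
  dplyr::bind_rows(chunks) |>
    dplyr::arrange(.data$person_id, .data$.item_order) |>
    dplyr::mutate(survey_datetime = "2022-06-30T12:00:00Z") |>
    dplyr::select(-".item_order")
}

#' Write a synthetic cohort's response table to CSV
#'
#' Writes the exact dialect [read_responses()] reads.
#'
#' @param cohort A list from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort$responses |>
    dplyr::transmute(person_id = .data$person_id,
                     question_concept_id = .data$question_code,
                     question = "", answer_concept_id = .data$answer_code,
                     answer = .data$answer_text,
                     answer_numeric = .data$answer_numeric,
                     survey_datetime = .data$survey_datetime)
  qtext <- sdoh_registry()$items$question_text[
    match(out$question_concept_id, sdoh_registry()$items$question_code)]
  out$question <- ifelse(is.na(qtext), "", qtext)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
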