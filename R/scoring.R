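# Scoring engine: complete-case calculation with NA reinsertion for the 30
# scoring options. Each score keeps every participant: anyone missing a
# required item gets NA rather than being dropped.

#' Score one scoring option from an item matrix
#'
#' Applies the option's reducer over its required items, on complete cases
#' only; participants missing any required item receive `NA` but remain in
#' the output.
#'
#' @param matrix An `sdoh_item_matrix` built by [map_answers()] for the
#'   option's construct, with polarity applied ([apply_polarity()]) for
#'   constructs that reverse-score items.
#' @param option_id One of the 30 option ids, e.g. `"df_cohesion"`,
#'   `"df_edd_chronicity"`; see `sdoh_registry()$scoring$option_id`.
#' @param registry An `sdoh_registry`.
#' @return A tibble with columns `person_id`, `score`, `option_id`. `score`
#'   is numeric or a character label depending on the option.
#' @examples
#' resp <- fixture_participants()
#' m <- apply_polarity(map_answers(resp, "cohesion"))
#' score_option(m, "df_cohesion")
#' @export
score_option <- function(matrix, option_id, registry = sdoh_registry()) {
  opt <- .scoring_option(registry, option_id)
  construct <- attr(matrix, "construct")
  if (!identical(construct, opt$construct)) {
    stop("option '", option_id, "' scores construct '", opt$construct,
         "' but the matrix holds '", construct %||% "<unknown>", "'",
         call. = FALSE)
  }
  if (!identical(attr(matrix, "value_map") %||% "standard", opt$value_map)) {
    stop("option '", option_id, "' needs a matrix built with value_map = '",
         opt$value_map, "'", call. = FALSE)
  }
  items <- .construct_items(registry, construct)
  needs_polarity <- any(items$polarity == "reversed" &
                          items$item_index %in% opt$items[[1]])
  if (needs_polarity && !isTRUE(attr(matrix, "polarity_applied"))) {
    stop("option '", option_id, "' requires apply_polarity() first",
         call. = FALSE)
  }
  req <- items[items$item_index %in% opt$items[[1]], ]
  score <- .reduce_option(matrix, opt, req, registry)
  tibble::tibble(person_id = matrix$person_id, score = score,
                 option_id = opt$option_id)
}

.col_missing <- function(col) {
  if (is.list(col)) vapply(col, is.null, logical(1)) else is.na(col)
}

.reduce_option <- function(matrix, opt, req, registry) {
  n <- nrow(matrix)
  reducer <- opt$reducer
  qcs <- req$question_code

  if (reducer %in% c("mean", "sum", "transformed_mean_0_100", "situation",
                     "chronicity", "never_ever", "count")) {
    vals <- as.matrix(as.data.frame(matrix[, qcs, drop = FALSE]))
    complete <- rowSums(is.na(vals)) == 0L
    out <- rep(NA_real_, n)
    if (any(complete)) {
      v <- vals[complete, , drop = FALSE]
      out[complete] <- switch(reducer,
        mean = rowMeans(v),
        sum = rowSums(v),
        # item average rescaled from [smin, smax] to 0-100
        transformed_mean_0_100 = {
          smin <- req$scale_min[1]; smax <- req$scale_max[1]
          100 * (rowMeans(v) - smin) / (smax - smin)
        },
        situation = rowSums(v > 1),
        chronicity = {
          cm <- registry$chronicity_map
          rowSums(matrix(cm[as.character(v)], nrow = nrow(v)))
        },
        count = rowSums(v > 1),
        never_ever = as.numeric(rowSums(v > 1) > 0)
      )
    }
    if (reducer == "never_ever") {
      lab <- opt$labels[[1]]   # c("none", "any")
      return(ifelse(is.na(out), NA_character_, lab[out + 1]))
    }
    return(out)
  }

  switch(reducer,
    nei = {
      # one point per activity-favorable response: agree-side (3-4) Likert
      # answers; any housing type other than detached single-family
      pts <- matrix(NA_real_, nrow = n, ncol = nrow(req))
      for (k in seq_len(nrow(req))) {
        col <- matrix[[req$question_code[k]]]
        pts[, k] <- if (identical(req$subscale[k], "density")) {
          ifelse(is.na(col), NA_real_, as.numeric(col != .density_low))
        } else {
          ifelse(is.na(col), NA_real_, as.numeric(col >= 3))
        }
      }
      out <- rowSums(pts)
      out
    },
    screen_any = {
      # Hunger Vital Sign: either item often/sometimes true flags risk
      lab <- opt$labels[[1]]
      a <- matrix[[qcs[1]]]; b <- matrix[[qcs[2]]]
      endorsed <- c("Often true", "Sometimes true")
      ifelse(is.na(a) | is.na(b), NA_character_,
             ifelse(a %in% endorsed | b %in% endorsed, lab[2], lab[1]))
    },
    threshold_moves = {
      lab <- opt$labels[[1]]
      moves <- matrix[[qcs[1]]]
      ifelse(is.na(moves), NA_character_, ifelse(moves >= 2, lab[2], lab[1]))
    },
    checklist_need = {
      lab <- opt$labels[[1]]
      sets <- matrix[[qcs[1]]]
      vapply(sets, function(s) {
        if (is.null(s)) return(NA_character_)
        problems <- setdiff(s, "None of the above")
        if (length(problems) && "None of the above" %in% s) {
          warning("housing checklist endorses problems alongside ",
                  "'None of the above'; problems win", call. = FALSE)
        }
        if (length(problems)) lab[2] else lab[1]
      }, character(1))
    },
    pss_category = {
      total <- .reduce_option(matrix, dplyr::mutate(opt, reducer = "sum"),
                              req, registry)
      cut_pss(total)
    },
    relabel = {
      col <- matrix[[qcs[1]]]
      as.character(col)
    },
    english_ordinal = {
      gate <- matrix[[qcs[1]]]; sub <- matrix[[qcs[2]]]
      ifelse(is.na(gate) | gate != "Yes", NA_character_, sub)
    },
    english_collapsed = {
      gate <- matrix[[qcs[1]]]; sub <- matrix[[qcs[2]]]
      collapsed <- dplyr::case_match(
        sub,
        c("Very well", "Well") ~ "proficient",
        c("Not well", "Not at all") ~ "not proficient",
        c("Prefer not to answer", "Don't know") ~ "unknown"
      )
      ifelse(is.na(gate) | gate != "Yes", NA_character_, collapsed)
    },
    stop("unknown reducer: ", reducer, call. = FALSE)
  )
}

#' Categorize a perceived-stress total
#'
#' Applies the printed PSS-10 cut points: totals 0-13 are "low stress", 14-26
#' "moderate stress", 27-40 "high stress". `NA` totals give `NA`.
#'
#' @param total Numeric vector of PSS-10 totals (0-40).
#' @return Character vector of stress categories.
#' @export
cut_pss <- function(total) {
  dplyr::case_when(
    is.na(total) ~ NA_character_,
    total <= 13 ~ "low stress",
    total <= 26 ~ "moderate stress",
    TRUE ~ "high stress"
  )
}

# Build the (polarity-applied) matrix an option needs, starting from the
# long response table.
.matrix_for_option <- function(responses, opt, registry) {
  m <- map_answers(responses, opt$construct, registry,
                   value_map = opt$value_map)
  apply_polarity(m, registry)
}

#' Score a single option straight from a response table
#'
#' Convenience wrapper chaining [map_answers()], [apply_polarity()] and
#' [score_option()].
#'
#' @inheritParams score_option
#' @param responses A long response tibble.
#' @return A tibble `person_id`, `score`, `option_id`.
#' @export
score_responses <- function(responses, option_id, registry = sdoh_registry()) {
  opt <- .scoring_option(registry, option_id)
  score_option(.matrix_for_option(responses, opt, registry), option_id,
               registry)
}

#' Compute all 30 scoring options
#'
#' Runs every scoring option in the registry over a long response table.
#' Every participant present in `responses` appears exactly once in every
#' score table, with `NA` where a required item is missing (the complete-case
#' contract).
#'
#' @param responses A long response tibble ([read_responses()] or
#'   [generate_cohort()]).
#' @param registry An `sdoh_registry`.
#' @param options Optional character vector of option ids to compute
#'   (default: all).
#' @return A named list of score tibbles, one per option id.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' scores <- score_all(cohort$responses)
#' scores$df_cohesion
#' @export
score_all <- function(responses, registry = sdoh_registry(), options = NULL) {
  scoring <- registry$scoring
  if (!is.null(options)) {
    bad <- setdiff(options, scoring$option_id)
    if (length(bad)) {
      stop("unknown scoring option(s): ", paste(bad, collapse = ", "),
           "; valid options: ", paste(scoring$option_id, collapse = ", "),
           call. = FALSE)
    }
    scoring <- scoring[scoring$option_id %in% options, ]
  }
  # build each needed (construct, value_map) matrix once
  keys <- unique(scoring[, c("construct", "value_map")])
  mats <- list()
  for (i in seq_len(nrow(keys))) {
    key <- paste(keys$construct[i], keys$value_map[i], sep = "/")
    m <- map_answers(responses, keys$construct[i], registry,
                     value_map = keys$value_map[i])
    mats[[key]] <- apply_polarity(m, registry)
  }
  out <- lapply(seq_len(nrow(scoring)), function(i) {
    opt <- scoring[i, ]
    key <- paste(opt$construct, opt$value_map, sep = "/")
    score_option(mats[[key]], opt$option_id, registry)
  })
  stats::setNames(out, scoring$option_id)
}

#' Pivot a list of score tables to one wide tibble
#'
#' @param scores A named list of score tibbles from [score_all()].
#' @return A tibble keyed by `person_id` with one column per scoring option.
#' @export
scores_wide <- function(scores) {
  stopifnot(is.list(scores), length(scores) > 0)
  out <- tibble::tibble(person_id = scores[[1]]$person_id)
  for (nm in names(scores)) {
    stopifnot(identical(scores[[nm]]$person_id, out$person_id))
    out[[nm]] <- scores[[nm]]$score
  }
  out
}

#' Write score tables to CSV
#'
#' Writes either one `scores_<option>.csv` per option or, with
#' `wide = TRUE`, a single `scores_wide.csv` keyed by `person_id`. `NA`
#' renders as an empty field; numeric scores are written at full precision.
#'
#' @param scores Named list of score tibbles from [score_all()].
#' @param dir Output directory (created if needed).
#' @param wide Write a single wide CSV instead of per-option files.
#' @return Paths of the written files, invisibly.
#' @export
write_scores <- function(scores, dir, wide = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (wide) {
    path <- file.path(dir, "scores_wide.csv")
    readr::write_csv(scores_wide(scores), path, na = "")
    return(invisible(path))
  }
  paths <- vapply(names(scores), function(nm) {
    path <- file.path(dir, paste0("scores_", nm, ".csv"))
    readr::write_csv(scores[[nm]][, c("person_id", "score")], path, na = "")
    path
  }, character(1))
  invisible(paths)
}
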