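#' The survey scoring registry
#'
#' The registry is the machine-readable description of the Social Determinants
#' of Health Survey that drives every other function in the package: the 14
#' constructs and their 80 items, each item's response vocabulary and polarity,
#' and the catalogue of 30 scoring options (multiple options for 8 of the
#' constructs).
#'
#' Question and answer codes in the built-in registry are deterministic
#' placeholders (e.g. `"SDOH_COHESION_1"`). Real Researcher Workbench concept
#' IDs can be bound with a YAML config, see [load_registry()].
#'
#' @param config Optional path to a YAML override config (see
#'   [load_registry()]).
#' @return An object of class `sdoh_registry`: a list with tibbles `items`,
#'   `options` (answer-code to value/label maps), `scoring` (the 30 scoring
#'   options) and the named numeric `chronicity_map` used by annualized
#'   discrimination scoring.
#' @examples
#' reg <- sdoh_registry()
#' reg
#' dplyr::count(reg$items[reg$items$counted, ], construct)
#' @export
sdoh_registry <- function(config = NULL) {
  items <- .default_items()
  reg <- structure(
    list(
      items = items,
      options = .default_options(items),
      scoring = .default_scoring(),
      chronicity_map = .default_chronicity_map
    ),
    class = "sdoh_registry"
  )
  if (!is.null(config)) reg <- .apply_registry_config(reg, config)
  reg
}

#' Load a registry, optionally rebinding concept codes from a config file
#'
#' The config is a YAML file with any of the keys:
#' \describe{
#'   \item{`question_codes`}{named map from placeholder question codes to the
#'     codes found in your export (e.g. numeric `question_concept_id`s).}
#'   \item{`answer_codes`}{named map from placeholder answer codes to
#'     `answer_concept_id`s.}
#'   \item{`chronicity_map`}{named map (names `"1"`..`"6"`) giving annualized
#'     event counts per everyday-discrimination response category.}
#'   \item{`reversed_items`}{map from construct name to the integer item
#'     indexes that should be reverse-scored (replaces the default polarity
#'     of that construct's scale items).}
#' }
#'
#' @param path Path to the YAML config, or `NULL` for the built-in default.
#' @return An `sdoh_registry` object.
#' @seealso [validate_registry()], [write_registry()]
#' @export
load_registry <- function(path = NULL) {
  sdoh_registry(config = path)
}

.apply_registry_config <- function(reg, config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("registry config not found: ", config, call. = FALSE)
    }
    tryCatch(yaml::read_yaml(config), error = function(e) {
      stop("malformed registry config '", config, "': ", conditionMessage(e),
           call. = FALSE)
    })
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a file path or a list", call. = FALSE)
  }
  known <- c("question_codes", "answer_codes", "chronicity_map", "reversed_items")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown registry config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$question_codes)) {
    qmap <- unlist(cfg$question_codes)
    unknown <- setdiff(names(qmap), reg$items$question_code)
    if (length(unknown)) {
      stop("config rebinds unknown question code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    rebind <- function(x) dplyr::if_else(x %in% names(qmap),
                                         unname(qmap[x]), x)
    reg$items$question_code <- rebind(reg$items$question_code)
    reg$items$branching_parent <- dplyr::if_else(
      is.na(reg$items$branching_parent), reg$items$branching_parent,
      rebind(reg$items$branching_parent))
    reg$options$question_code <- rebind(reg$options$question_code)
  }
  if (!is.null(cfg$answer_codes)) {
    amap <- unlist(cfg$answer_codes)
    unknown <- setdiff(names(amap), reg$options$answer_code)
    if (length(unknown)) {
      stop("config rebinds unknown answer code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg$options$answer_code <- dplyr::if_else(
      reg$options$answer_code %in% names(amap),
      unname(amap[reg$options$answer_code]), reg$options$answer_code)
  }
  if (!is.null(cfg$chronicity_map)) {
    cm <- unlist(cfg$chronicity_map)
    if (!setequal(names(cm), names(.default_chronicity_map))) {
      stop("chronicity_map must name categories 1..6", call. = FALSE)
    }
    reg$chronicity_map[names(cm)] <- as.numeric(cm)
  }
  if (!is.null(cfg$reversed_items)) {
    for (construct in names(cfg$reversed_items)) {
      idx <- as.integer(unlist(cfg$reversed_items[[construct]]))
      sel <- reg$items$construct == construct
      if (!any(sel)) {
        stop("reversed_items names unknown construct: ", construct,
             call. = FALSE)
      }
      reg$items$polarity[sel] <-
        dplyr::if_else(reg$items$item_index[sel] %in% idx, "reversed", "normal")
    }
  }
  reg
}

#' @export
print.sdoh_registry <- function(x, ...) {
  counted <- x$items[x$items$counted, ]
  cat("<sdoh_registry>\n")
  cat("  constructs:      ", dplyr::n_distinct(counted$construct), "\n")
  cat("  items:           ", nrow(counted),
      sprintf("(+%d branching sub-item)", sum(!x$items$counted)), "\n")
  cat("  scoring options: ", nrow(x$scoring), "\n")
  invisible(x)
}

#' Validate a registry against the survey's structural invariants
#'
#' Checks construct/item/option counts against the published survey structure
#' (14 constructs, 80 items, 30 scoring options), uniqueness of question
#' codes, scale bounds on scale-valued answer options, polarity restricted to
#' bounded scale items, and branching-parent consistency. Violations are
#' reported, not raised.
#'
#' @param registry An `sdoh_registry` object.
#' @return A tibble with columns `rule`, `construct`, `message`; zero rows if
#'   the registry is valid.
#' @examples
#' nrow(validate_registry(sdoh_registry())) # 0
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "sdoh_registry"))
  items <- registry$items
  counted <- items[items$counted, ]
  problems <- list()
  flag <- function(rule, construct, message) {
    problems[[length(problems) + 1L]] <<-
      tibble::tibble(rule = rule, construct = construct, message = message)
  }

  got <- table(counted$construct)
  for (con in names(.expected_item_counts)) {
    n <- if (con %in% names(got)) as.integer(got[[con]]) else 0L
    if (n != .expected_item_counts[[con]]) {
      flag("item_count", con,
           sprintf("item count %d != %d", n, .expected_item_counts[[con]]))
    }
  }
  extra <- setdiff(names(got), names(.expected_item_counts))
  for (con in extra) flag("unknown_construct", con, "construct not in the survey")
  if (nrow(counted) != 80L) {
    flag("total_items", NA_character_,
         sprintf("total item count %d != 80", nrow(counted)))
  }
  if (dplyr::n_distinct(counted$construct) != 14L) {
    flag("construct_count", NA_character_,
         sprintf("construct count %d != 14",
                 dplyr::n_distinct(counted$construct)))
  }
  if (nrow(registry$scoring) != 30L) {
    flag("option_count", NA_character_,
         sprintf("scoring option count %d != 30", nrow(registry$scoring)))
  }
  dup <- items$question_code[duplicated(items$question_code)]
  for (qc in unique(dup)) {
    flag("duplicate_question_code", NA_character_,
         sprintf("question code %s is duplicated", qc))
  }
  dup_ii <- dplyr::count(items, .data$construct, .data$item_index) |>
    dplyr::filter(.data$n > 1L)
  for (i in seq_len(nrow(dup_ii))) {
    flag("duplicate_item_index", dup_ii$construct[i],
         sprintf("item_index %d repeated", dup_ii$item_index[i]))
  }
  bad_rev <- items[items$polarity == "reversed" &
                     (is.na(items$scale_min) | is.na(items$scale_max)), ]
  for (i in seq_len(nrow(bad_rev))) {
    flag("reversed_without_scale", bad_rev$construct[i],
         sprintf("item %d reversed but has no scale bounds",
                 bad_rev$item_index[i]))
  }
  # scale_value options must fall inside the item's declared bounds
  sv <- dplyr::inner_join(
    registry$options[registry$options$role == "scale_value", ],
    items[, c("question_code", "construct", "item_index", "scale_min", "scale_max")],
    by = "question_code", relationship = "many-to-many")
  oob <- sv[!is.na(sv$scale_min) &
              (sv$value < sv$scale_min | sv$value > sv$scale_max), ]
  for (i in seq_len(nrow(oob))) {
    flag("option_out_of_bounds", oob$construct[i],
         sprintf("item %d option %s value %g outside [%g, %g]",
                 oob$item_index[i], oob$answer_code[i], oob$value[i],
                 oob$scale_min[i], oob$scale_max[i]))
  }
  kids <- items[!is.na(items$branching_parent), ]
  for (i in seq_len(nrow(kids))) {
    if (!kids$branching_parent[i] %in% items$question_code) {
      flag("branching_parent_missing", kids$construct[i],
           sprintf("item %d names absent parent %s", kids$item_index[i],
                   kids$branching_parent[i]))
    }
  }
  # every scoring option must point at real items of its construct
  for (i in seq_len(nrow(registry$scoring))) {
    opt <- registry$scoring[i, ]
    have <- items$item_index[items$construct == opt$construct]
    miss <- setdiff(opt$items[[1]], have)
    if (length(miss)) {
      flag("option_items_missing", opt$construct,
           sprintf("option %s requires absent item(s) %s", opt$option_id,
                   paste(miss, collapse = ", ")))
    }
  }
  if (length(problems)) dplyr::bind_rows(problems) else {
    tibble::tibble(rule = character(), construct = character(),
                   message = character())
  }
}

# --- serialization -----------------------------------------------------------

.tbl_to_yaml_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df[i, ], function(col) {
      v <- if (is.list(col)) col[[1]] else col
      if (length(v) == 1 && is.na(v) && !is.list(v)) NULL else v
    })
    row[!vapply(row, is.null, logical(1))]
  })
}

.yaml_col <- function(rows, name, coerce, default) {
  vapply(rows, function(r) {
    if (is.null(r[[name]])) default else coerce(r[[name]])
  }, default)
}

.yaml_list_col <- function(rows, name, coerce) {
  lapply(rows, function(r) coerce(unlist(r[[name]]) %||% coerce(c())))
}

#' Write a registry to a YAML file
#'
#' The written file reloads with [read_registry()] to an identical registry,
#' so a registry can be dumped, hand-edited (e.g. to rebind concept codes or
#' flip item polarities) and reloaded.
#'
#' @param registry An `sdoh_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "sdoh_registry"))
  yaml::write_yaml(
    list(
      chronicity_map = as.list(registry$chronicity_map),
      items = .tbl_to_yaml_list(registry$items),
      options = .tbl_to_yaml_list(registry$options),
      scoring = .tbl_to_yaml_list(registry$scoring)
    ),
    path
  )
  invisible(path)
}

#' Read a registry written by [write_registry()]
#'
#' @param path Path to a registry YAML file.
#' @return An `sdoh_registry`.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- tibble::tibble(
    construct = .yaml_col(raw$items, "construct", as.character, NA_character_),
    item_index = .yaml_col(raw$items, "item_index", as.integer, NA_integer_),
    question_code = .yaml_col(raw$items, "question_code", as.character, NA_character_),
    question_text = .yaml_col(raw$items, "question_text", as.character, NA_character_),
    item_kind = .yaml_col(raw$items, "item_kind", as.character, NA_character_),
    scale_min = .yaml_col(raw$items, "scale_min", as.numeric, NA_real_),
    scale_max = .yaml_col(raw$items, "scale_max", as.numeric, NA_real_),
    polarity = .yaml_col(raw$items, "polarity", as.character, NA_character_),
    subscale = .yaml_col(raw$items, "subscale", as.character, NA_character_),
    vocab = .yaml_col(raw$items, "vocab", as.character, NA_character_),
    counted = .yaml_col(raw$items, "counted", as.logical, NA),
    branching_parent = .yaml_col(raw$items, "branching_parent", as.character, NA_character_),
    branching_trigger = .yaml_col(raw$items, "branching_trigger", as.character, NA_character_)
  )
  options <- tibble::tibble(
    question_code = .yaml_col(raw$options, "question_code", as.character, NA_character_),
    answer_code = .yaml_col(raw$options, "answer_code", as.character, NA_character_),
    answer_text = .yaml_col(raw$options, "answer_text", as.character, NA_character_),
    value = .yaml_col(raw$options, "value", as.numeric, NA_real_),
    value_alt = .yaml_col(raw$options, "value_alt", as.numeric, NA_real_),
    label = .yaml_col(raw$options, "label", as.character, NA_character_),
    role = .yaml_col(raw$options, "role", as.character, NA_character_)
  )
  scoring <- tibble::tibble(
    option_id = .yaml_col(raw$scoring, "option_id", as.character, NA_character_),
    construct = .yaml_col(raw$scoring, "construct", as.character, NA_character_),
    reducer = .yaml_col(raw$scoring, "reducer", as.character, NA_character_),
    output_kind = .yaml_col(raw$scoring, "output_kind", as.character, NA_character_),
    items = .yaml_list_col(raw$scoring, "items", as.integer),
    range_min = .yaml_col(raw$scoring, "range_min", as.numeric, NA_real_),
    range_max = .yaml_col(raw$scoring, "range_max", as.numeric, NA_real_),
    labels = .yaml_list_col(raw$scoring, "labels", as.character),
    value_map = .yaml_col(raw$scoring, "value_map", as.character, NA_character_)
  )
  cm <- unlist(raw$chronicity_map)
  structure(
    list(items = items, options = options, scoring = scoring,
         chronicity_map = stats::setNames(as.numeric(cm), names(cm))),
    class = "sdoh_registry"
  )
}

# items tibble rows for one construct, ordered by item_index
.construct_items <- function(registry, construct) {
  out <- registry$items[registry$items$construct == construct, ]
  if (!nrow(out)) stop("unknown construct: ", construct, call. = FALSE)
  dplyr::arrange(out, .data$item_index)
}

.scoring_option <- function(registry, option_id) {
  row <- registry$scoring[registry$scoring$option_id == option_id, ]
  if (!nrow(row)) {
    stop("unknown scoring option '", option_id, "'; valid options: ",
         paste(registry$scoring$option_id, collapse = ", "), call. = FALSE)
  }
  row
}
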