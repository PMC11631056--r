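# Internal consistency reporting. Cronbach's alpha over complete cases of a
# construct's numeric scale items, conventionally computed after reverse
# scoring (pass a polarity-applied matrix).

#' Cronbach's alpha for a construct's item matrix
#'
#' Computes `alpha = (k/(k-1)) * (1 - sum(item variances) / variance(total))`
#' over complete cases of the construct's numeric scale items, together with
#' alpha-if-item-deleted diagnostics. Variances are sample (n-1) variances.
#'
#' Polarity matters: alpha is conventionally computed after reverse scoring,
#' so pass the matrix through [apply_polarity()] first (as [alpha_table()]
#' does).
#'
#' @param matrix An `sdoh_item_matrix` from [map_answers()] /
#'   [apply_polarity()].
#' @param registry An `sdoh_registry`.
#' @param item_indexes Optional integer vector restricting the computation to
#'   a subset of the construct's items (e.g. a subscale); default all scale
#'   items.
#' @return An object of class `sdoh_alpha`: list with `construct`, `k`
#'   (item count), `n_complete`, `alpha`, and an `item_stats` tibble
#'   (`question_code`, `mean`, `sd`, `alpha_if_deleted`). Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50, seed = 1))
#' m <- apply_polarity(map_answers(cohort$responses, "loneliness"))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(matrix, registry = sdoh_registry(),
                           item_indexes = NULL) {
  construct <- attr(matrix, "construct")
  items <- .construct_items(registry, construct)
  items <- items[items$item_kind %in% c("likert", "count") &
                   !is.na(items$scale_min) & items$counted, ]
  if (!is.null(item_indexes)) {
    items <- items[items$item_index %in% item_indexes, ]
  }
  k <- nrow(items)
  if (k < 2) {
    stop("internal consistency needs at least 2 scale items; '", construct,
         "' has ", k, call. = FALSE)
  }
  V <- as.matrix(as.data.frame(matrix[, items$question_code, drop = FALSE]))
  V <- V[stats::complete.cases(V), , drop = FALSE]
  n <- nrow(V)
  if (n < 3) {
    stop("insufficient data: ", n, " complete case(s) for '", construct,
         "' (need at least 3)", call. = FALSE)
  }
  alpha_of <- function(M) {
    total_var <- stats::var(rowSums(M))
    if (total_var == 0) {
      stop("alpha undefined: total-score variance is zero for '", construct,
           "'", call. = FALSE)
    }
    kk <- ncol(M)
    (kk / (kk - 1)) * (1 - sum(apply(M, 2, stats::var)) / total_var)
  }
  alpha <- alpha_of(V)
  aid <- vapply(seq_len(k), function(j) {
    tryCatch(alpha_of(V[, -j, drop = FALSE]), error = function(e) NA_real_)
  }, numeric(1))
  structure(
    list(
      construct = construct, k = k, n_complete = n, alpha = alpha,
      item_stats = tibble::tibble(
        question_code = items$question_code,
        mean = colMeans(V),
        sd = apply(V, 2, stats::sd),
        alpha_if_deleted = aid
      )
    ),
    class = "sdoh_alpha"
  )
}

#' @export
print.sdoh_alpha <- function(x, ...) {
  cat(sprintf("<sdoh_alpha> %s: alpha = %.3f (k = %d, n complete = %d)\n",
              x$construct, x$alpha, x$k, x$n_complete))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an internal-consistency report
#'
#' @param x An `sdoh_alpha` object.
#' @param ... Unused.
#' @return `tidy()`: per-item tibble with `question_code`, `mean`, `sd`,
#'   `alpha_if_deleted`. `glance()`: one-row tibble with `construct`, `k`,
#'   `n_complete`, `alpha`.
#' @export
tidy.sdoh_alpha <- function(x, ...) {
  x$item_stats
}

#' @rdname tidy.sdoh_alpha
#' @export
glance.sdoh_alpha <- function(x, ...) {
  tibble::tibble(construct = x$construct, k = x$k,
                 n_complete = x$n_complete, alpha = x$alpha)
}

#' Internal-consistency table for every multi-item scale
#'
#' Runs [cronbach_alpha()] for every construct with two or more numeric scale
#' items (after reverse scoring). Constructs that fail preconditions (too few
#' complete cases, zero variance) are reported as rows with a `note`, not
#' raised as errors.
#'
#' @param responses A long response tibble.
#' @param registry An `sdoh_registry`.
#' @return A tibble with `construct`, `k`, `n_complete`, `alpha`, `note`.
#' @export
alpha_table <- function(responses, registry = sdoh_registry()) {
  items <- registry$items
  multi <- items |>
    dplyr::filter(.data$item_kind %in% c("likert", "count"),
                  !is.na(.data$scale_min), .data$counted) |>
    dplyr::count(.data$construct) |>
    dplyr::filter(.data$n >= 2)
  purrr::map_dfr(multi$construct, function(con) {
    m <- apply_polarity(map_answers(responses, con, registry), registry)
    tryCatch({
      a <- cronbach_alpha(m, registry)
      tibble::tibble(construct = con, k = a$k, n_complete = a$n_complete,
                     alpha = a$alpha, note = NA_character_)
    }, error = function(e) {
      tibble::tibble(construct = con, k = NA_integer_, n_complete = NA_integer_,
                     alpha = NA_real_, note = conditionMessage(e))
    })
  })
}
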