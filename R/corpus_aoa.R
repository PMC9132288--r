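# First-occurrence extraction and k-child corpus AoA estimates.

#' Extract per-child first occurrences
#'
#' For every (child, word) pair with at least one attestation, records the
#' earliest session age at which the child produced the word.  Words whose
#' first attestation falls in a child's first session are flagged as
#' left-censored: the word may have been acquired before recording began,
#' so the first-session age is only an upper bound on the true onset.
#'
#' @param session_table Session table from [read_chat_corpus()] or
#'   [sessions_to_table()].
#' @return Tibble with columns `child_id`, `word`, `first_age_months`,
#'   `censored` (logical).
#' @export
extract_first_occurrences <- function(session_table) {
  dup <- session_table |>
    dplyr::count(.data$child_id, .data$session_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (child, session_index) pairs: ",
         paste(dup$child_id, dup$session_index, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  first_session <- session_table |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(first_session_age = min(.data$age_months))
  session_word_table(session_table) |>
    dplyr::group_by(.data$child_id, .data$word) |>
    dplyr::summarise(first_age_months = min(.data$age_months),
                     .groups = "drop") |>
    dplyr::left_join(first_session, by = "child_id") |>
    dplyr::mutate(censored = .data$first_age_months <=
                    .data$first_session_age,
                  first_session_age = NULL)
}

#' k-child corpus AoA estimates
#'
#' Retains words attested in at least `k` children and aggregates the
#' per-child first-occurrence ages into one AoA value per word.  The
#' default aggregation follows the convention that the 1-child estimate is
#' the earliest occurrence in any child, while multi-child estimates
#' (k >= 2) use the mean first-occurrence age over all attesting children.
#'
#' @param first_occ First-occurrence table from
#'   [extract_first_occurrences()].
#' @param k Minimum number of attesting children.
#' @param aggregator `"auto"` (min when k = 1, mean otherwise), `"min"`,
#'   or `"mean"`.
#' @return Tibble with columns `word`, `variant` (= k), `n_children`,
#'   `aoa_months`.
#' @export
kchild_aoa <- function(first_occ, k, aggregator = c("auto", "min", "mean")) {
  aggregator <- match.arg(aggregator)
  stopifnot(k >= 1, nrow(first_occ) > 0)
  if (aggregator == "auto") aggregator <- if (k == 1) "min" else "mean"
  n_children_total <- dplyr::n_distinct(first_occ$child_id)
  if (k > n_children_total) {
    warning("k = ", k, " exceeds the number of children (",
            n_children_total, "); empty result", call. = FALSE)
  }
  agg_fun <- switch(aggregator, min = min, mean = mean)
  first_occ |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(n_children = dplyr::n(),
                     aoa_months = round(agg_fun(.data$first_age_months), 2),
                     .groups = "drop") |>
    dplyr::filter(.data$n_children >= k) |>
    dplyr::mutate(variant = as.integer(k), .after = "word") |>
    dplyr::arrange(.data$word)
}

#' Word and first-occurrence counts per k-threshold
#'
#' For each threshold `k`, counts the number of distinct words attested in
#' at least `k` children and the total number of per-child first
#' occurrences among those words.
#'
#' @param first_occ First-occurrence table.
#' @param k_list Integer vector of thresholds (default `c(1, 6, 12)`).
#' @return Tibble with columns `k`, `n_words`, `n_first_occurrences`.
#' @export
corpus_summary <- function(first_occ, k_list = c(1L, 6L, 12L)) {
  stopifnot(nrow(first_occ) > 0)
  per_word <- dplyr::count(first_occ, .data$word, name = "n_children")
  purrr::map_dfr(sort(k_list), function(k) {
    kept <- dplyr::filter(per_word, .data$n_children >= k)
    tibble::tibble(k = as.integer(k),
                   n_words = nrow(kept),
                   n_first_occurrences = sum(kept$n_children))
  })
}

#' Write corpus AoA outputs as delimited text
#'
#' @param aoa_table Combined k-child AoA table (rows from [kchild_aoa()]).
#' @param first_occ First-occurrence table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_corpus_aoa <- function(aoa_table, first_occ, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(file.path(dir, "corpus_aoa.csv"),
             file.path(dir, "first_occurrences.csv"))
  readr::write_csv(aoa_table, paths[1])
  readr::write_csv(first_occ, paths[2])
  invisible(paths)
}
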