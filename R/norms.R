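# Parent-report AoA50 from CDI curves; harmonization of adult-rating AoA,
# test-based AoA, child frequency, and lexical decision norms; frequency
# adjustment; word-keyed join.

#' Fit the 50%-acquisition age (AoA50) for one word
#'
#' Fits a binomial GLM with logit link to proportion-saying-by-age data,
#' `logit(p) = b0 + b1 * age`, and returns the age at which the fitted
#' curve crosses 50% (`logit(p) = 0`), i.e. `aoa50 = -b0 / b1`.  Fits
#' with a non-positive slope or a crossing outside the admissible range
#' are excluded: a flat or decreasing curve gives an extrapolated crossing
#' with no behavioural meaning.
#'
#' @param curve Data frame with columns `age_months`, `n_saying`,
#'   `n_total` (one row per age).
#' @param admissible_range Ages (months) within which the crossing is
#'   accepted (default `c(6, 60)`).
#' @return One-row tibble: `aoa50_months`, `slope`, `converged`,
#'   `excluded_reason` (`"none"`, `"no_convergence"`,
#'   `"non_positive_slope"`, `"out_of_range"`).
#' @export
fit_aoa50 <- function(curve, admissible_range = c(6, 60)) {
  stopifnot(all(c("age_months", "n_saying", "n_total") %in% names(curve)),
            all(curve$n_saying <= curve$n_total),
            all(curve$n_total >= 1),
            dplyr::n_distinct(curve$age_months) >= 2)
  fit <- tryCatch(
    suppressWarnings(stats::glm(
      cbind(n_saying, n_total - n_saying) ~ age_months,
      family = stats::binomial(), data = curve)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(tibble::tibble(aoa50_months = NA_real_, slope = NA_real_,
                          converged = FALSE,
                          excluded_reason = "no_convergence"))
  }
  b <- stats::coef(fit)
  slope <- unname(b[2])
  if (!is.finite(slope) || slope <= 0) {
    return(tibble::tibble(aoa50_months = NA_real_, slope = slope,
                          converged = TRUE,
                          excluded_reason = "non_positive_slope"))
  }
  aoa50 <- -unname(b[1]) / slope
  if (aoa50 < admissible_range[1] || aoa50 > admissible_range[2]) {
    return(tibble::tibble(aoa50_months = NA_real_, slope = slope,
                          converged = TRUE,
                          excluded_reason = "out_of_range"))
  }
  tibble::tibble(aoa50_months = aoa50, slope = slope, converged = TRUE,
                 excluded_reason = "none")
}

#' Fit AoA50 for every word in a CDI table
#'
#' @param cdi Long-format CDI data: `word`, `age_months`, `n_saying`,
#'   `n_total`.
#' @param admissible_range Passed to [fit_aoa50()].
#' @return Tibble with one row per word: `word`, `aoa50_months`, `slope`,
#'   `converged`, `excluded_reason`.
#' @export
fit_aoa50_all <- function(cdi, admissible_range = c(6, 60)) {
  cdi |>
    dplyr::group_by(.data$word) |>
    dplyr::group_modify(~ fit_aoa50(.x, admissible_range)) |>
    dplyr::ungroup()
}

#' Merge multiple meanings of test-based AoA entries
#'
#' Test-based norms assign a grade level per (word, meaning); polysemous
#' words are merged by taking the lowest grade over meanings, i.e. the
#' earliest acquisition among the word's senses.
#'
#' @param entries Data frame with columns `word`, `meaning` (ignored
#'   beyond grouping), `grade`.
#' @param admissible_grades Allowed grade levels (default
#'   `c(2, 4, 6, 8, 10, 12, 13, 14)`).
#' @return Tibble `word`, `test_aoa_grade`.
#' @export
merge_test_meanings <- function(entries,
                                admissible_grades = c(2, 4, 6, 8, 10, 12,
                                                      13, 14)) {
  stopifnot(all(entries$grade %in% admissible_grades))
  entries |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(test_aoa_grade = min(.data$grade), .groups = "drop")
}

#' Child log-frequency from two age-band counts
#'
#' The child frequency of a word is the arithmetic mean of its per-million
#' frequencies in the preschool (0-6 years) and primary-school (6-12
#' years) bands, entered on the natural-log scale.  Words with zero mean
#' frequency get `NA` (no smoothing by default; set `epsilon` to add a
#' small constant before the log).
#'
#' @param freq Data frame with columns `word`, `freq_preschool`,
#'   `freq_primary` (per-million counts).
#' @param epsilon Optional additive smoothing constant (default 0).
#' @return Tibble `word`, `child_log_freq`.
#' @export
child_log_frequency <- function(freq, epsilon = 0) {
  if (any(freq$freq_preschool < 0 | freq$freq_primary < 0)) {
    stop("negative frequency", call. = FALSE)
  }
  freq |>
    dplyr::mutate(.mean = (.data$freq_preschool + .data$freq_primary) / 2 +
                    epsilon,
                  child_log_freq = ifelse(.data$.mean > 0, log(.data$.mean),
                                          NA_real_)) |>
    dplyr::select("word", "child_log_freq")
}

#' Frequency-adjusted AoA by residualization
#'
#' Regresses AoA on log-frequency by ordinary least squares over the FULL
#' set of words with both values, and returns the residuals.  Residuals
#' for any word subset must come from this single full-sample fit — never
#' refit within a subset — so that the adjustment removes the global
#' sampling advantage of frequent words.
#'
#' @param aoa Numeric vector of AoA values.
#' @param log_freq Numeric vector of log-frequencies, same length.
#' @return Numeric vector of residuals (`NA` where either input is `NA`),
#'   with attributes `slope` and `intercept` of the full-sample fit.
#' @export
adjust_for_frequency <- function(aoa, log_freq) {
  stopifnot(length(aoa) == length(log_freq))
  ok <- !is.na(aoa) & !is.na(log_freq)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(log_freq[ok]) == 0) {
    stop("zero variance in log-frequency", call. = FALSE)
  }
  fit <- stats::lm(aoa[ok] ~ log_freq[ok])
  out <- rep(NA_real_, length(aoa))
  out[ok] <- stats::residuals(fit)
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  out
}

#' Join word norms into one word-keyed table
#'
#' Case-insensitive exact-string join over any number of word-keyed
#' sources.  Each source must have a `word` column and unique words;
#' duplicates raise an error naming the offenders.  Rows where every
#' non-key column is missing are dropped.
#'
#' @param ... Named data frames, each keyed by `word`.
#' @return Tibble keyed by (lower-cased) `word` containing the union of
#'   all source columns.
#' @export
join_norms <- function(...) {
  sources <- list(...)
  if (is.null(names(sources)) || any(names(sources) == "")) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  sources <- purrr::imap(sources, function(src, nm) {
    stopifnot("word" %in% names(src))
    src <- dplyr::mutate(src, word = tolower(.data$word))
    dups <- unique(src$word[duplicated(src$word)])
    if (length(dups) > 0) {
      stop("duplicate words in source ", sQuote(nm), ": ",
           paste(utils::head(dups, 10), collapse = ", "), call. = FALSE)
    }
    src
  })
  joined <- purrr::reduce(sources, dplyr::full_join, by = "word")
  value_cols <- setdiff(names(joined), "word")
  keep <- rowSums(!is.na(joined[value_cols])) > 0
  dplyr::arrange(joined[keep, , drop = FALSE], .data$word)
}

#' Restrict a norm table to complete cases on required columns
#'
#' @param table Word-keyed norm table.
#' @param required Character vector of column names that must be
#'   non-missing.
#' @return Tibble of complete rows; the number of rows is the word-set
#'   size reported for the analysis.
#' @export
complete_word_set <- function(table, required) {
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  table[stats::complete.cases(table[required]), , drop = FALSE]
}

#' Read a delimited norm table with a column map
#'
#' Thin reader for CSV/TSV norm files: renames the declared columns to the
#' package's canonical names and keeps only those.
#'
#' @param path Delimited text file.
#' @param col_map Named character vector, `canonical = file_column`; must
#'   include `word`.
#' @param delim Field delimiter (guessed from the extension by default).
#' @return Tibble with the canonical columns.
#' @export
read_norm_table <- function(path, col_map, delim = NULL) {
  stopifnot("word" %in% names(col_map))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[unname(col_map)]
  names(out) <- names(col_map)
  out
}
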