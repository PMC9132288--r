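# End-to-end orchestration: extract -> corpus AoA -> reliability -> norms
# -> validation, on real CHAT input or a synthetic world, with a manifest.

#' Build a pipeline configuration
#'
#' Collects every knob of the analysis flow.  Exactly one of `chat_dir`
#' (a directory of `.cha` files plus norm-table paths) or
#' `synthetic_params` (a [world_params()] object) must be given.  All
#' defaults mirror the study design the package models: k-thresholds 1,
#' 6 and 12; Pearson correlations; corpus AoA entered unadjusted in the
#' RT regressions; 5-fold cross-validation with 4 repeats.
#'
#' @param chat_dir Directory of CHAT transcripts (real-data mode).
#' @param norm_paths Named list of file paths (`cdi`, `ratings`, `freq`,
#'   `rt`) with columns as written by [write_synthetic_bundle()] or
#'   remapped via `col_maps`.
#' @param col_maps Optional named list of column maps (see
#'   [read_norm_table()]) per norm table.
#' @param synthetic_params A [world_params()] object (synthetic mode).
#' @param k_thresholds Integer vector of k-child thresholds.
#' @param aggregator Aggregation policy for [kchild_aoa()].
#' @param cor_method Correlation method.
#' @param adjust_corpus_aoa Use frequency-adjusted corpus AoA in the RT
#'   regressions instead of the raw estimate (default `FALSE`).
#' @param cv_folds,cv_repeats Cross-validation settings.
#' @param n_splits Split-half partitions.
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(chat_dir = NULL, norm_paths = NULL, col_maps = NULL,
                       synthetic_params = NULL,
                       k_thresholds = c(1L, 6L, 12L),
                       aggregator = "auto",
                       cor_method = "pearson",
                       adjust_corpus_aoa = FALSE,
                       cv_folds = 5L, cv_repeats = 4L,
                       n_splits = 100L, seed, out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("config error: seed is mandatory", call. = FALSE)
  }
  if (is.null(chat_dir) == is.null(synthetic_params)) {
    stop("config error: give exactly one of chat_dir or synthetic_params",
         call. = FALSE)
  }
  k_thresholds <- sort(as.integer(k_thresholds))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: session extraction (from `.cha` files or a
#' simulated corpus), first-occurrence extraction, k-child AoA for every
#' threshold, reliability per threshold, AoA50 fits and norm joining,
#' frequency adjustment, correlation matrices per word set, and the two
#' regression batteries on lexical decision times (without and with
#' parent-report AoA as a predictor), each with repeated k-fold
#' cross-validation.  Artifacts are written under `out_dir` when set.
#'
#' @param config A [run_config()] object.
#' @return A list with `manifest` plus all stage outputs (`first_occ`,
#'   `aoa`, `reliability`, `norm_table`, `word_sets`, `correlations`,
#'   `regressions`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  manifest <- list(config = config_echo(cfg),
                   version = as.character(utils::packageVersion("aoacorpus")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   counts = list(), warnings = character(0))

  # stage 1: sessions + norm sources
  if (!is.null(cfg$synthetic_params)) {
    world <- simulate_world(cfg$synthetic_params)
    sessions <- simulate_corpus(world)
    norms_raw <- simulate_ratings_freq_rt(world)
    cdi <- simulate_cdi(world)
    ratings <- norms_raw$ratings
    freq <- norms_raw$freq
    rt <- norms_raw$rt
  } else {
    sessions <- read_chat_corpus(cfg$chat_dir)
    cm <- cfg$col_maps %||% list()
    cdi <- read_norm_table(cfg$norm_paths$cdi,
                           cm$cdi %||% c(word = "word",
                                         age_months = "age_months",
                                         n_saying = "n_saying",
                                         n_total = "n_total"))
    ratings <- read_norm_table(cfg$norm_paths$ratings,
                               cm$ratings %||%
                                 c(word = "word",
                                   rating_aoa_years = "rating_aoa_years"))
    freq <- read_norm_table(cfg$norm_paths$freq,
                            cm$freq %||% c(word = "word",
                                           freq_preschool = "freq_preschool",
                                           freq_primary = "freq_primary",
                                           freq_adult = "freq_adult"))
    rt <- read_norm_table(cfg$norm_paths$rt,
                          cm$rt %||% c(word = "word", rt_ms = "rt_ms"))
  }
  manifest$counts$n_sessions <- nrow(sessions)
  manifest$counts$n_children <- dplyr::n_distinct(sessions$child_id)

  # stage 2: first occurrences and k-child AoA
  first_occ <- extract_first_occurrences(sessions)
  manifest$counts$n_first_occurrences <- nrow(first_occ)
  aoa_tables <- lapply(cfg$k_thresholds, function(k) {
    kchild_aoa(first_occ, k, cfg$aggregator)
  })
  names(aoa_tables) <- paste0("k", cfg$k_thresholds)
  manifest$counts$n_words_per_k <-
    stats::setNames(vapply(aoa_tables, nrow, integer(1)),
                    names(aoa_tables))

  # stage 3: reliability per threshold
  reliability <- lapply(cfg$k_thresholds, function(k) {
    reliability_report(first_occ, k, n_splits = cfg$n_splits,
                       seed = derive_seed(cfg$seed, 10L + k))
  })
  names(reliability) <- names(aoa_tables)

  # stage 4: norms
  aoa50 <- fit_aoa50_all(cdi)
  manifest$counts$n_aoa50_fit <- sum(aoa50$excluded_reason == "none")
  clf <- child_log_frequency(freq)
  alf <- dplyr::transmute(freq, word = .data$word,
                          adult_log_freq = ifelse(.data$freq_adult > 0,
                                                  log(.data$freq_adult),
                                                  NA_real_))
  corpus_wide <- purrr::reduce(
    purrr::imap(aoa_tables, function(tab, nm) {
      stats::setNames(tab[c("word", "aoa_months")],
                      c("word", paste0("corpus_aoa_", nm)))
    }),
    dplyr::full_join, by = "word")
  norm_table <- join_norms(
    corpus = corpus_wide,
    ratings = ratings,
    parent = dplyr::select(aoa50, "word",
                           parent_aoa50_months = "aoa50_months"),
    child_freq = clf,
    adult_freq = alf,
    rt = rt)
  # frequency adjustment: one full-sample fit per corpus variant
  for (nm in names(aoa_tables)) {
    col <- paste0("corpus_aoa_", nm)
    adj <- adjust_for_frequency(norm_table[[col]],
                                norm_table$child_log_freq)
    norm_table[[paste0("adj_", col)]] <- as.numeric(adj)
  }
  manifest$counts$n_norm_rows <- nrow(norm_table)

  # stage 5: validation per word set
  correlations <- list()
  regressions <- list()
  word_sets <- list()
  for (nm in names(aoa_tables)) {
    col <- paste0("corpus_aoa_", nm)
    adj_col <- paste0("adj_", col)
    reg_col <- if (cfg$adjust_corpus_aoa) adj_col else col
    cor_vars <- c("rating_aoa_years", col, adj_col, "child_log_freq")
    word_sets[[nm]] <- nrow(complete_word_set(norm_table, cor_vars))
    correlations[[nm]] <- correlation_matrix(norm_table, cor_vars,
                                             cfg$cor_method)
    preds3 <- c(reg_col, "rating_aoa_years", "adult_log_freq")
    preds4 <- c(preds3, "parent_aoa50_months")
    regressions[[nm]] <- list(
      rt_base = regress_with_cv(norm_table, "rt_ms", preds3, cfg),
      rt_parent = regress_with_cv(norm_table, "rt_ms", preds4, cfg))
  }
  manifest$counts$word_set_sizes <- word_sets
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  result <- list(manifest = manifest, first_occ = first_occ,
                 aoa = aoa_tables, reliability = reliability,
                 aoa50 = aoa50, norm_table = norm_table,
                 word_sets = word_sets, correlations = correlations,
                 regressions = regressions)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

regress_with_cv <- function(norm_table, outcome, predictors, cfg) {
  reg <- standardized_regression(norm_table, outcome, predictors)
  cv <- cross_validate(norm_table, outcome, predictors,
                       folds = cfg$cv_folds, repeats = cfg$cv_repeats,
                       seed = derive_seed(cfg$seed, 20L))
  list(regression = reg, cv = cv,
       table = regression_table(reg, cv))
}

config_echo <- function(cfg) {
  echo <- unclass(cfg)
  if (!is.null(echo$synthetic_params)) {
    echo$synthetic_params <- unclass(echo$synthetic_params)
  }
  echo
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$first_occ,
                   file.path(out_dir, "first_occurrences.csv"))
  readr::write_csv(dplyr::bind_rows(result$aoa),
                   file.path(out_dir, "corpus_aoa.csv"))
  readr::write_csv(result$aoa50, file.path(out_dir, "aoa50.csv"))
  readr::write_csv(result$norm_table, file.path(out_dir, "norm_table.csv"))
  for (nm in names(result$correlations)) {
    cm <- result$correlations[[nm]]
    readr::write_csv(tibble::as_tibble(cm$r, rownames = "variable"),
                     file.path(out_dir, paste0("correlations_", nm, ".csv")))
  }
  reg_rows <- purrr::imap_dfr(result$regressions, function(models, nm) {
    dplyr::bind_rows(
      dplyr::mutate(models$rt_base$table, word_set = nm,
                    model = "rt_base"),
      dplyr::mutate(models$rt_parent$table, word_set = nm,
                    model = "rt_parent"))
  })
  readr::write_csv(reg_rows, file.path(out_dir, "regressions.csv"))
  rel <- purrr::imap_dfr(result$reliability, function(r, nm) {
    tibble::tibble(variant = r$variant, icc2k = r$icc2k,
                   split_half_r = r$split_half_r,
                   n_words_used = r$n_words_used,
                   n_splits = r$n_splits, seed = r$seed)
  })
  readr::write_csv(rel, file.path(out_dir, "reliability.csv"))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
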