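small_params <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_children = 4, n_sessions = 12, n_words = 50,
         tokens_per_session = 100, seed = seed),
    list(...))
  do.call(world_params, args)
}

test_that("the same seed reproduces the world exactly", {
  w1 <- simulate_world(small_params(101))
  w2 <- simulate_world(small_params(101))
  expect_identical(w1, w2)
  expect_identical(simulate_corpus(w1), simulate_corpus(w2))
  expect_identical(simulate_cdi(w1), simulate_cdi(w2))
  expect_identical(simulate_ratings_freq_rt(w1),
                   simulate_ratings_freq_rt(w2))
  w3 <- simulate_world(small_params(102))
  expect_false(identical(w1$words, w3$words))
})

test_that("world parameters are validated", {
  expect_error(world_params(), "seed")
  expect_error(world_params(cdi_slope = -1, seed = 1))
  expect_error(world_params(rt_freq_coeff = 2, seed = 1))
  expect_error(world_params(session_gap_days = c(14, 10), seed = 1))
})

test_that("zero child variance makes all children share word AoA", {
  w <- simulate_world(small_params(7, child_sd_months = 0))
  expect_true(all(apply(w$child_aoa, 1, function(x) diff(range(x)) == 0)))
})

test_that("schedule respects the gap range and snaps to the age grid", {
  w <- simulate_world(small_params(8))
  per_child <- split(w$sessions$age_months, w$sessions$child_id)
  for (ages in per_child) {
    gaps_days <- diff(ages) * 30.44
    expect_true(all(gaps_days > 9 & gaps_days < 15))
  }
  # ages survive the CHAT age-string round trip unchanged
  expect_identical(
    parse_age(vapply(w$sessions$age_months,
                     aoacorpus:::months_to_age_string, character(1))),
    w$sessions$age_months)
})

test_that("usage rates follow the configured Zipf law", {
  w <- simulate_world(world_params(n_words = 1000, zipf_exponent = 1,
                                   seed = 3))
  rate <- sort(w$words$usage_rate, decreasing = TRUE)
  fit <- stats::lm(log(rate) ~ log(seq_along(rate)))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-6)
})

test_that("no word is ever attested before its latent acquisition age", {
  w <- simulate_world(small_params(9))
  fo <- extract_first_occurrences(simulate_corpus(w))
  truth <- tibble::as_tibble(w$child_aoa, rownames = "word") |>
    tidyr::pivot_longer(-word, names_to = "child_id",
                        values_to = "true_aoa")
  joined <- dplyr::inner_join(fo, truth, by = c("child_id", "word"))
  expect_identical(nrow(joined), nrow(fo))
  expect_true(all(joined$first_age_months >= joined$true_aoa))
})

test_that("extreme usage rates pin first occurrence to acquisition", {
  w <- simulate_world(small_params(10, tokens_per_session = 1e6,
                                   zipf_exponent = 0))
  fo <- extract_first_occurrences(simulate_corpus(w))
  sessions <- w$sessions
  for (i in seq_len(nrow(fo))) {
    ages <- sessions$age_months[sessions$child_id == fo$child_id[i]]
    acq <- w$child_aoa[fo$word[i], fo$child_id[i]]
    first_eligible <- min(ages[ages >= acq])
    expect_identical(fo$first_age_months[i], first_eligible)
  }
})

test_that("a zero usage rate removes the word from the corpus", {
  w <- simulate_world(small_params(11))
  w$words$usage_rate[1] <- 0
  corp <- simulate_corpus(w)
  expect_false(w$words$word[1] %in% unlist(corp$word_types))
})

test_that("CDI curves cross 50% at the true acquisition age", {
  w <- simulate_world(small_params(12))
  cdi <- simulate_cdi(w, ages = seq(12, 48, 2), n_per_age = 400)
  # empirical proportion at the age nearest each word's true AoA ~ 0.5
  near <- dplyr::inner_join(cdi, w$words, by = "word") |>
    dplyr::group_by(word) |>
    dplyr::slice_min(abs(age_months - true_aoa_months), n = 1,
                     with_ties = FALSE) |>
    dplyr::ungroup()
  expect_lt(abs(mean(near$n_saying / near$n_total) - 0.5), 0.1)
})

test_that("fit_aoa50 recovers true AoA from generated CDI curves", {
  w <- simulate_world(small_params(13))
  cdi <- simulate_cdi(w, ages = seq(12, 48, 1), n_per_age = 100)
  res <- fit_aoa50_all(cdi)
  joined <- dplyr::inner_join(res, w$words, by = "word") |>
    dplyr::filter(excluded_reason == "none")
  expect_gt(nrow(joined), 40)
  expect_lt(stats::median(abs(joined$aoa50_months -
                                joined$true_aoa_months)), 1)
})

test_that("noise-free uncontaminated ratings are an affine image of truth", {
  w <- simulate_world(small_params(14, rating_noise_sd = 0,
                                   rating_contamination_weight = 0))
  r <- simulate_ratings_freq_rt(w)$ratings
  expect_equal(cor_oracle(r$rating_aoa_years, w$words$true_aoa_months), 1,
               tolerance = 1e-12)
})

test_that("contamination links ratings to frequency beyond true AoA", {
  w <- simulate_world(small_params(15, rating_noise_sd = 0,
                                   rating_contamination_weight = 0.3))
  r <- simulate_ratings_freq_rt(w)$ratings
  partial <- stats::lm(rating_aoa_years ~ true_aoa + log_rate,
                       data = tibble::tibble(
                         rating_aoa_years = r$rating_aoa_years,
                         true_aoa = w$words$true_aoa_months,
                         log_rate = log(w$words$usage_rate)))
  expect_lt(coef(partial)["log_rate"], 0)  # rarer words rated later
})

test_that("the synthetic bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  w <- simulate_world(small_params(16))
  write_synthetic_bundle(w, dir, cdi_ages = seq(16, 36, 4),
                         cdi_n_per_age = 20)
  reread <- read_chat_corpus(file.path(dir, "chat"))
  direct <- simulate_corpus(w)
  expect_identical(reread$age_months, direct$age_months)
  expect_identical(reread$word_types, direct$word_types)
  cdi <- readr::read_csv(file.path(dir, "cdi.csv"),
                         show_col_types = FALSE)
  expect_identical(nrow(cdi), nrow(simulate_cdi(w, seq(16, 36, 4), 20L)))
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
                           show_col_types = FALSE)
  expect_identical(nrow(truth), 50L * 4L)
})
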