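exact_curve <- function(b0, b1, ages, n = 50) {
  tibble::tibble(age_months = ages,
                 n_saying = n * plogis(b0 + b1 * ages),
                 n_total = n)
}

test_that("fit_aoa50 recovers the crossing analytically", {
  # data generated exactly on the curve: MLE equals the generating curve
  res <- fit_aoa50(exact_curve(-12, 0.5, 16:30))
  expect_equal(res$aoa50_months, 24.0, tolerance = 1e-6)
  expect_equal(res$slope, 0.5, tolerance = 1e-6)
  expect_identical(res$excluded_reason, "none")
})

test_that("fit_aoa50 excludes flat, decreasing and out-of-range curves", {
  none <- tibble::tibble(age_months = 16:30, n_saying = 0, n_total = 50)
  expect_true(is.na(fit_aoa50(none)$aoa50_months))
  falling <- fit_aoa50(exact_curve(12, -0.5, 16:30))
  expect_identical(falling$excluded_reason, "non_positive_slope")
  late <- fit_aoa50(exact_curve(-12, 0.5, 16:30),
                    admissible_range = c(30, 60))  # crossing at 24
  expect_identical(late$excluded_reason, "out_of_range")
  expect_true(is.na(late$aoa50_months))
})

test_that("fit_aoa50 is equivariant under age shifts", {
  withr::with_seed(44, {
    ages <- 16:30
    curve <- tibble::tibble(
      age_months = ages,
      n_saying = rbinom(length(ages), 50, plogis(-12 + 0.5 * ages)),
      n_total = 50)
  })
  base <- fit_aoa50(curve)$aoa50_months
  shifted <- curve
  shifted$age_months <- shifted$age_months + 7
  expect_equal(fit_aoa50(shifted)$aoa50_months, base + 7,
               tolerance = 1e-8)
})

test_that("fit_aoa50_all fits each word separately", {
  cdi <- dplyr::bind_rows(
    dplyr::mutate(exact_curve(-12, 0.5, 16:30), word = "early"),
    dplyr::mutate(exact_curve(-15, 0.5, 16:40), word = "late"))
  res <- fit_aoa50_all(cdi)
  expect_equal(res$aoa50_months[res$word == "early"], 24, tolerance = 1e-6)
  expect_equal(res$aoa50_months[res$word == "late"], 30, tolerance = 1e-6)
})

test_that("merge_test_meanings takes the lowest grade, order-invariant", {
  entries <- tibble::tibble(word = c("bank", "bank", "run", "run", "run",
                                     "cup"),
                            meaning = c("money", "river", "move", "manage",
                                        "stocking", "drink"),
                            grade = c(4, 6, 2, 10, 13, 2))
  res <- merge_test_meanings(entries)
  expect_identical(res$test_aoa_grade[res$word == "bank"], 4)
  expect_identical(res$test_aoa_grade[res$word == "run"], 2)
  expect_identical(res$test_aoa_grade[res$word == "cup"], 2)
  rev_res <- merge_test_meanings(entries[rev(seq_len(nrow(entries))), ])
  expect_identical(res, rev_res)
  expect_error(merge_test_meanings(tibble::tibble(word = "x", meaning = "m",
                                                  grade = 3)))
})

test_that("child_log_frequency averages the two bands on the log scale", {
  freq <- tibble::tibble(word = c("a", "b", "c"),
                         freq_preschool = c(10, 5, 0),
                         freq_primary = c(30, 5, 0))
  res <- child_log_frequency(freq)
  expect_equal(res$child_log_freq, c(log(20), log(5), NA_real_))
  expect_error(child_log_frequency(
    tibble::tibble(word = "x", freq_preschool = -1, freq_primary = 2)),
    "negative")
  # epsilon smoothing keeps zero-frequency words
  sm <- child_log_frequency(freq, epsilon = 0.5)
  expect_equal(sm$child_log_freq[3], log(0.5))
})

test_that("adjust_for_frequency residuals are orthogonal to the regressor", {
  withr::with_seed(9, {
    lf <- rnorm(200, 3, 1)
    aoa <- 30 - 2 * lf + rnorm(200, 0, 2)
  })
  res <- adjust_for_frequency(aoa, lf)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(cor_oracle(as.numeric(res), lf)), 1e-10)
  expect_equal(attr(res, "slope"), -2, tolerance = 0.3)
  # orthogonal fixture: slope 0, residuals are centered AoA
  aoa2 <- rep(c(20, 30, 20, 30), 25)
  lf2 <- rep(c(1, 1, 2, 2), 25)  # balanced, uncorrelated with aoa2
  res2 <- adjust_for_frequency(aoa2, lf2)
  expect_equal(as.numeric(res2), aoa2 - mean(aoa2), tolerance = 1e-10)
})

test_that("adjust_for_frequency keeps NA alignment and validates input", {
  aoa <- c(24, NA, 28, 30, 26)
  lf <- c(1, 2, NA, 4, 2)
  res <- adjust_for_frequency(aoa, lf)
  expect_identical(is.na(as.numeric(res)), c(FALSE, TRUE, TRUE, FALSE,
                                             FALSE))
  expect_error(adjust_for_frequency(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(adjust_for_frequency(c(1, 2, 3), c(2, 2, 2)),
               "zero variance")
})

test_that("subset residuals generally correlate with frequency again", {
  # the adjustment must come from the FULL fit: within a frequency-biased
  # subset the residuals are no longer orthogonal to log-frequency
  withr::with_seed(13, {
    lf <- rnorm(500, 3, 1)
    aoa <- 30 - 2 * lf + rnorm(500, 0, 1) + 0.5 * lf^2
  })
  res <- as.numeric(adjust_for_frequency(aoa, lf))
  sub <- lf > 3
  expect_lt(abs(cor_oracle(res, lf)), 1e-10)
  expect_gt(abs(cor_oracle(res[sub], lf[sub])), 0.1)
})

test_that("join_norms performs a case-folded word join", {
  a <- tibble::tibble(word = c("Ball", "dog", "cup"), x = 1:3)
  b <- tibble::tibble(word = c("ball", "dog", "shoe"), y = 4:6)
  j <- join_norms(a = a, b = b)
  expect_setequal(j$word, c("ball", "dog", "cup", "shoe"))
  expect_identical(j$x[j$word == "ball"], 1L)
  expect_identical(j$y[j$word == "ball"], 4L)
  expect_error(join_norms(a = tibble::tibble(word = c("x", "X"), v = 1:2)),
               "duplicate")
})

test_that("complete-case restriction matches brute-force intersection", {
  a <- tibble::tibble(word = c("a", "b", "c"), x = c(1, NA, 3))
  b <- tibble::tibble(word = c("b", "c", "d"), y = c(1, 2, 3))
  c_ <- tibble::tibble(word = c("a", "c", "d"), z = c(1, 2, NA))
  j <- join_norms(a = a, b = b, c = c_)
  full <- complete_word_set(j, c("x", "y", "z"))
  # brute force: words with a non-missing value in every source
  want <- Reduce(intersect, list(a$word[!is.na(a$x)], b$word[!is.na(b$y)],
                                 c_$word[!is.na(c_$z)]))
  expect_setequal(full$word, want)
  expect_error(complete_word_set(j, "nope"), "not in table")
})

test_that("read_norm_table applies the declared column map", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(WORD = c("a", "b"), RTms = c(500, 600)),
                   path)
  tab <- read_norm_table(path, c(word = "WORD", rt_ms = "RTms"))
  expect_identical(names(tab), c("word", "rt_ms"))
  expect_error(read_norm_table(path, c(word = "WORD", rt_ms = "missing")),
               "not found")
})
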