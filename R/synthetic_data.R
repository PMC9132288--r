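# Synthetic longitudinal worlds with known latent truth: per-word mean
# acquisition ages, per-child deviations, Zipfian usage rates, a
# 10-14-day recording schedule, CDI acquisition curves, adult ratings,
# frequencies and lexical decision times.

#' Parameters of a synthetic world
#'
#' Defaults emulate a 12-child longitudinal study: 36 recording sessions
#' per child, 10 to 14 days apart, starting near age 24 months so the
#' corpus covers roughly ages 2 to 3.  Word mean acquisition ages are
#' lognormal (median 22 months, 0.25 log-units); children deviate from
#' each word's mean by Gaussian offsets truncated at a 10-month floor;
#' per-session word usage follows a Zipfian rate distribution thinned by a
#' Poisson token model; parent-report curves are logistic in age around
#' the word's mean acquisition age; adult ratings are a noisy affine image
#' of true AoA with an optional frequency contamination; lexical decision
#' times increase with true AoA and decrease with log-frequency.
#'
#' @param n_children,n_sessions Number of children and sessions per child.
#' @param session_gap_days Length-2 range of uniform gaps between
#'   sessions, in days.
#' @param age_start_months Age at the first session.
#' @param n_words Vocabulary size of the world.
#' @param aoa_meanlog,aoa_sdlog Lognormal parameters of word mean AoA in
#'   months.
#' @param child_sd_months SD of per-child AoA deviations.
#' @param aoa_floor_months Truncation floor for child acquisition ages.
#' @param zipf_exponent Zipf exponent of the usage-rate distribution.
#' @param tokens_per_session Expected child tokens per session (scales
#'   every word's Poisson rate).
#' @param cdi_slope Logistic slope of the parent-report curve, per month.
#' @param rating_intercept_years,rating_slope_per_month Affine map from
#'   true AoA (months) to rated AoA (years).
#' @param rating_noise_sd Rating noise SD, years.
#' @param rating_contamination_weight Weight of `-log(usage rate)` in the
#'   rating: > 0 makes adults rate rare words as later-acquired
#'   independently of true AoA.
#' @param freq_noise_sdlog Lognormal jitter of the per-million frequency
#'   bands around the usage rate.
#' @param rt_intercept_ms,rt_aoa_coeff,rt_freq_coeff,rt_noise_sd Linear RT
#'   model: `RT = intercept + aoa_coeff * trueAoA + freq_coeff * logfreq +
#'   noise`; the AoA coefficient must be positive and the frequency
#'   coefficient negative.
#' @param seed Integer seed (mandatory); all generators are pure functions
#'   of the parameters and this seed.
#' @return A `world_params` list.
#' @export
world_params <- function(n_children = 12L,
                         n_sessions = 36L,
                         session_gap_days = c(10, 14),
                         age_start_months = 24,
                         n_words = 600L,
                         aoa_meanlog = log(22),
                         aoa_sdlog = 0.25,
                         child_sd_months = 3,
                         aoa_floor_months = 10,
                         zipf_exponent = 1,
                         tokens_per_session = 300,
                         cdi_slope = 0.5,
                         rating_intercept_years = 1,
                         rating_slope_per_month = 0.15,
                         rating_noise_sd = 0.5,
                         rating_contamination_weight = 0.1,
                         freq_noise_sdlog = 0.2,
                         rt_intercept_ms = 600,
                         rt_aoa_coeff = 2,
                         rt_freq_coeff = -10,
                         rt_noise_sd = 30,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_children >= 1, n_sessions >= 1,
            length(session_gap_days) == 2,
            session_gap_days[1] > 0,
            session_gap_days[2] >= session_gap_days[1],
            n_words >= 1, aoa_sdlog >= 0, child_sd_months >= 0,
            cdi_slope > 0, rating_noise_sd >= 0,
            rt_aoa_coeff > 0, rt_freq_coeff < 0, rt_noise_sd >= 0)
  structure(as.list(environment()), class = "world_params")
}

#' Simulate the latent world
#'
#' Draws word mean acquisition ages and Zipfian usage rates, per-child
#' acquisition-age deviations, and each child's recording schedule
#' (uniform 10-14-day gaps accumulated from the starting age, snapped to
#' the two-decimal month grid used by the CHAT age headers).
#'
#' @param params A [world_params()] list.
#' @return A `synthetic_world` list: `params`, `words` (tibble `word`,
#'   `true_aoa_months`, `usage_rate` = expected tokens/session),
#'   `child_aoa` (words x children matrix of true acquisition ages),
#'   `sessions` (tibble `child_id`, `session_index`, `age_months`).
#' @export
simulate_world <- function(params) {
  stopifnot(inherits(params, "world_params"))
  p <- params
  withr::with_seed(p$seed, {
    word <- sprintf("w%04d", seq_len(p$n_words))
    true_aoa <- stats::rlnorm(p$n_words, p$aoa_meanlog, p$aoa_sdlog)
    # Zipfian usage: rate of the r-th ranked word proportional to r^-s
    prob <- seq_len(p$n_words)^(-p$zipf_exponent)
    prob <- sample(prob)               # decouple rank from word index
    prob <- prob / sum(prob)
    usage_rate <- p$tokens_per_session * prob
    children <- sprintf("c%02d", seq_len(p$n_children))
    dev <- matrix(stats::rnorm(p$n_words * p$n_children, 0,
                               p$child_sd_months),
                  nrow = p$n_words)
    child_aoa <- pmax(true_aoa + dev, p$aoa_floor_months)
    dimnames(child_aoa) <- list(word, children)
    gaps <- matrix(stats::runif(p$n_children * (p$n_sessions - 1),
                                p$session_gap_days[1],
                                p$session_gap_days[2]),
                   nrow = p$n_children)
    ages <- matrix(0, p$n_children, p$n_sessions)
    for (j in seq_len(p$n_sessions)[-1]) {
      ages[, j] <- ages[, j - 1] + gaps[, j - 1]
    }
    ages <- ages / 30.44 + p$age_start_months
    sessions <- tibble::tibble(
      child_id = rep(children, each = p$n_sessions),
      session_index = rep(seq_len(p$n_sessions), times = p$n_children),
      age_months = parse_age(vapply(as.vector(t(ages)),
                                    months_to_age_string, character(1))))
  })
  structure(
    list(params = p,
         words = tibble::tibble(word = word, true_aoa_months = true_aoa,
                                usage_rate = usage_rate),
         child_aoa = child_aoa,
         sessions = sessions),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d children x %d sessions, %d words, seed %d\n",
              x$params$n_children, x$params$n_sessions, x$params$n_words,
              x$params$seed))
  invisible(x)
}

#' Simulate the longitudinal corpus
#'
#' For each session at age t, every word already acquired by the child
#' (true acquisition age <= t) contributes a Poisson token count at its
#' usage rate; unacquired words contribute nothing, so no word can ever be
#' attested before its latent acquisition age.  Returns a session table in
#' the same shape as [read_chat_corpus()] output.
#'
#' @param world A `synthetic_world`.
#' @return Tibble `child_id`, `session_index`, `age_months`, `word_types`
#'   (list-column of word types observed in the session).
#' @export
simulate_corpus <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- world$params
  lambda <- world$words$usage_rate
  word <- world$words$word
  out <- world$sessions
  types <- vector("list", nrow(out))
  withr::with_seed(derive_seed(p$seed, 1L), {
    for (i in seq_len(nrow(out))) {
      acq <- world$child_aoa[, out$child_id[i]] <= out$age_months[i]
      idx <- which(acq & lambda > 0)
      counts <- stats::rpois(length(idx), lambda[idx])
      types[[i]] <- sort(word[idx][counts > 0])
    }
  })
  out$word_types <- types
  out
}

#' Simulate parent-report (CDI) curves
#'
#' At each age t, the number of children reported to say word w is
#' binomial with probability `plogis(cdi_slope * (t - trueAoA_w))`; the
#' 50% crossing of the generating curve is the word's true mean
#' acquisition age by construction.
#'
#' @param world A `synthetic_world`.
#' @param ages Ages (months) at which children are sampled.
#' @param n_per_age Number of children per age.
#' @return Long-format tibble `word`, `age_months`, `n_saying`, `n_total`.
#' @export
simulate_cdi <- function(world, ages = seq(12, 48, by = 2),
                         n_per_age = 50L) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- world$params
  grid <- tidyr::expand_grid(word = world$words$word, age_months = ages)
  grid <- dplyr::left_join(grid,
                           world$words[c("word", "true_aoa_months")],
                           by = "word")
  withr::with_seed(derive_seed(p$seed, 2L), {
    pr <- stats::plogis(p$cdi_slope *
                          (grid$age_months - grid$true_aoa_months))
    grid$n_saying <- stats::rbinom(nrow(grid), n_per_age, pr)
  })
  grid$n_total <- as.integer(n_per_age)
  grid$true_aoa_months <- NULL
  grid
}

#' Simulate adult ratings, frequency norms, and lexical decision times
#'
#' Ratings (in years) are an affine image of true AoA plus Gaussian noise,
#' optionally contaminated by `-log(usage rate)` so that rare words are
#' rated as later-acquired regardless of when children actually acquire
#' them.  The frequency table exposes per-million rates in a preschool and
#' a primary-school band (lognormal jitter around the usage rate) plus an
#' adult band.  RTs follow the linear model
#' `RT = intercept + aoa_coeff * trueAoA + freq_coeff * adult_log_freq +
#' noise`.
#'
#' @param world A `synthetic_world`.
#' @return List of tibbles: `ratings` (`word`, `rating_aoa_years`),
#'   `freq` (`word`, `freq_preschool`, `freq_primary`, `freq_adult`,
#'   per-million), `rt` (`word`, `rt_ms`).
#' @export
simulate_ratings_freq_rt <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- world$params
  w <- world$words
  n <- nrow(w)
  per_million <- 1e6 * w$usage_rate / sum(w$usage_rate)
  withr::with_seed(derive_seed(p$seed, 3L), {
    rating <- p$rating_intercept_years +
      p$rating_slope_per_month * w$true_aoa_months +
      p$rating_contamination_weight * (-log(w$usage_rate)) +
      stats::rnorm(n, 0, p$rating_noise_sd)
    freq_preschool <- per_million * exp(stats::rnorm(n, 0,
                                                     p$freq_noise_sdlog))
    freq_primary <- 0.8 * per_million * exp(stats::rnorm(n, 0,
                                                         p$freq_noise_sdlog))
    freq_adult <- per_million * exp(stats::rnorm(n, 0, p$freq_noise_sdlog))
    rt <- p$rt_intercept_ms + p$rt_aoa_coeff * w$true_aoa_months +
      p$rt_freq_coeff * log(freq_adult) +
      stats::rnorm(n, 0, p$rt_noise_sd)
  })
  list(
    ratings = tibble::tibble(word = w$word, rating_aoa_years = rating),
    freq = tibble::tibble(word = w$word, freq_preschool = freq_preschool,
                          freq_primary = freq_primary,
                          freq_adult = freq_adult),
    rt = tibble::tibble(word = w$word, rt_ms = rt))
}

#' Write a full synthetic bundle to disk
#'
#' Emits a directory tree of `.cha` files (one per session, one
#' subdirectory per child) plus `cdi.csv`, `ratings.csv`, `freq.csv`,
#' `rt.csv`, `truth.csv` and `params.json`, all readable by the package's
#' own readers.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory.
#' @param cdi_ages,cdi_n_per_age Passed to [simulate_cdi()].
#' @return Invisibly, `dir`.
#' @export
write_synthetic_bundle <- function(world, dir, cdi_ages = seq(12, 48, 2),
                                   cdi_n_per_age = 50L) {
  dir.create(file.path(dir, "chat"), recursive = TRUE, showWarnings = FALSE)
  corpus <- simulate_corpus(world)
  for (i in seq_len(nrow(corpus))) {
    s <- new_chat_session(corpus$child_id[i], corpus$session_index[i],
                          corpus$age_months[i], corpus$word_types[[i]])
    child_dir <- file.path(dir, "chat", s$child_id)
    dir.create(child_dir, showWarnings = FALSE)
    readr::write_lines(format_chat(s),
                       file.path(child_dir,
                                 sprintf("%s-%02d.cha", s$child_id,
                                         s$session_index)))
  }
  norms <- simulate_ratings_freq_rt(world)
  readr::write_csv(simulate_cdi(world, cdi_ages, cdi_n_per_age),
                   file.path(dir, "cdi.csv"))
  readr::write_csv(norms$ratings, file.path(dir, "ratings.csv"))
  readr::write_csv(norms$freq, file.path(dir, "freq.csv"))
  readr::write_csv(norms$rt, file.path(dir, "rt.csv"))
  truth <- dplyr::left_join(
    world$words,
    tidyr::pivot_longer(
      tibble::as_tibble(world$child_aoa, rownames = "word"),
      -"word", names_to = "child_id", values_to = "true_child_aoa"),
    by = "word")
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  params <- world$params
  class(params) <- NULL
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Derive a stream-specific 31-bit seed from the master seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
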