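# Independent oracle computations, deliberately coded against definitions
# (aov decompositions, explicit sums, exhaustive enumeration) rather than
# through the package's own code paths.

# ICC(2,k) from base-R aov mean squares.
icc2k_oracle <- function(m) {
  d <- data.frame(
    y = as.vector(m),
    w = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    r = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(y ~ w + r, data = d))[[1]][["Mean Sq"]]
  n <- nrow(m)
  (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
}

# Pearson correlation from the covariance definition.
cor_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Per-k word / first-occurrence counts by exhaustive enumeration over an
# attestation list.
corpus_summary_oracle <- function(first_occ, k_list) {
  words <- unique(first_occ$word)
  out <- NULL
  for (k in sort(k_list)) {
    nw <- 0L; nf <- 0L
    for (w in words) {
      kids <- unique(first_occ$child_id[first_occ$word == w])
      if (length(kids) >= k) {
        nw <- nw + 1L
        nf <- nf + length(kids)
      }
    }
    out <- rbind(out, data.frame(k = k, n_words = nw,
                                 n_first_occurrences = nf))
  }
  out
}

# A small deterministic first-occurrence table used across tests.
toy_first_occ <- function() {
  tibble::tribble(
    ~child_id, ~word,   ~first_age_months, ~censored,
    "A",       "ball",  24.0,              FALSE,
    "A",       "dog",   25.5,              FALSE,
    "A",       "cup",   26.0,              FALSE,
    "A",       "shoe",  27.0,              FALSE,
    "A",       "milk",  28.0,              FALSE,
    "B",       "ball",  25.0,              FALSE,
    "B",       "dog",   24.5,              FALSE,
    "B",       "cup",   27.5,              FALSE,
    "B",       "shoe",  26.5,              FALSE,
    "B",       "milk",  29.0,              FALSE)
}

# Build a session table directly from (child, age, words) triples.
make_sessions <- function(rows) {
  tibble::tibble(
    child_id = vapply(rows, `[[`, character(1), 1),
    session_index = vapply(rows, `[[`, numeric(1), 2) |> as.integer(),
    age_months = vapply(rows, `[[`, numeric(1), 3),
    word_types = lapply(rows, `[[`, 4))
}
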