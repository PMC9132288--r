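# Reliability of corpus AoA: ICC(2,k) with children as raters and words as
# subjects, and split-half correlation across random halves of the children.

#' Build a words-by-children rating matrix
#'
#' Rows are words, columns are children, cells are first-occurrence ages.
#' Children act as raters of the words' acquisition ages.  Cells are `NA`
#' where a child never produced the word.
#'
#' @param first_occ First-occurrence table from
#'   [extract_first_occurrences()].
#' @param min_children Keep only words attested in at least this many
#'   children (default 2).
#' @return Numeric matrix with word rownames and child colnames.
#' @export
rating_matrix <- function(first_occ, min_children = 2L) {
  wide <- first_occ |>
    dplyr::select("child_id", "word", "first_age_months") |>
    tidyr::pivot_wider(names_from = "child_id",
                       values_from = "first_age_months")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$word
  keep <- rowSums(!is.na(m)) >= min_children
  m[keep, , drop = FALSE]
}

#' Intraclass correlation ICC(2,k)
#'
#' Two-way random-effects intraclass correlation for the average of k
#' raters (Shrout & Fleiss ICC(2,k)): both words (subjects) and children
#' (raters) are random effects, and the reliability refers to the mean
#' rating over all raters.  From the two-way ANOVA mean squares,
#'
#'   ICC(2,k) = (BMS - EMS) / (BMS + (JMS - EMS) / n)
#'
#' with `n` words, `BMS` the between-words mean square, `JMS` the
#' between-raters mean square and `EMS` the residual mean square.
#'
#' The canonical path (`method = "complete"`) keeps only fully observed
#' rows, since the classical decomposition assumes a balanced design.  The
#' `"available"` path estimates the variance components from all available
#' cells with a crossed random-effects model (requires \pkg{lme4}) and is
#' labeled non-canonical: use it only when complete rows are too few.
#'
#' @param mat Words-by-raters numeric matrix (`NA` allowed).
#' @param method `"complete"` (default) or `"available"`.
#' @return ICC(2,k) value, or `NA` with a warning when it is not
#'   estimable (fewer than 2 complete rows, or no between-word variance).
#' @export
icc2k <- function(mat, method = c("complete", "available")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  if (method == "available") return(icc2k_available(mat))
  m <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) {
    warning("fewer than 2 complete rows; ICC not estimable", call. = FALSE)
    return(NA_real_)
  }
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  bss <- k * sum((row_means - grand)^2)          # between words
  jss <- n * sum((col_means - grand)^2)          # between raters
  tss <- sum((m - grand)^2)
  ess <- tss - bss - jss                         # residual
  bms <- bss / (n - 1)
  jms <- jss / (k - 1)
  ems <- ess / ((n - 1) * (k - 1))
  denom <- bms + (jms - ems) / n
  if (bms <= 0 || denom == 0) {
    warning("no between-word variance; ICC not estimable", call. = FALSE)
    return(NA_real_)
  }
  (bms - ems) / denom
}

# Variance-component route for incomplete matrices: crossed random effects
# for word and rater, ICC(2,k) = s2_w / (s2_w + (s2_r + s2_e) / k).
icc2k_available <- function(mat) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("the 'available' path requires the lme4 package", call. = FALSE)
  }
  long <- data.frame(
    value = as.vector(mat),
    word = factor(rep(rownames(mat), times = ncol(mat))),
    rater = factor(rep(colnames(mat), each = nrow(mat))))
  long <- long[!is.na(long$value), ]
  if (nrow(long) < 4) {
    warning("too few observed cells; ICC not estimable", call. = FALSE)
    return(NA_real_)
  }
  fit <- lme4::lmer(value ~ 1 + (1 | word) + (1 | rater), data = long,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- stats::setNames(vc$vcov, vc$grp)
  k <- ncol(mat)
  s2w <- s2[["word"]]
  s2r <- s2[["rater"]]
  s2e <- s2[["Residual"]]
  if (s2w + (s2r + s2e) / k == 0) return(NA_real_)
  s2w / (s2w + (s2r + s2e) / k)
}

#' Split-half reliability across children
#'
#' Children are randomly partitioned into two halves (sizes differing by
#' at most 1 when the count is odd).  Within each half, each word's AoA is
#' the mean first-occurrence age over the attesting children of that half;
#' the correlation is computed over words with a value in both halves, and
#' the returned value is the mean correlation over `n_splits` seeded
#' partitions.  Words attested by fewer than two children never contribute
#' (they cannot appear in both halves), so the 1-child variant is
#' automatically restricted to words produced by two or more children.
#'
#' @param first_occ First-occurrence table.
#' @param min_children Restrict to words attested in at least this many
#'   children overall (the k of the variant under study; values below 2
#'   are raised to 2).
#' @param n_splits Number of random partitions (default 100).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return List with `split_half_r` (mean over splits), `r_per_split`,
#'   `n_words_per_split`, `n_splits`, `seed`.
#' @export
split_half <- function(first_occ, min_children = 2L, n_splits = 100L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  min_children <- max(2L, as.integer(min_children))
  children <- sort(unique(first_occ$child_id))
  if (length(children) < 2) stop("need at least 2 children", call. = FALSE)
  eligible <- first_occ |>
    dplyr::add_count(.data$word, name = ".n_attest") |>
    dplyr::filter(.data$.n_attest >= min_children)
  withr::with_seed(seed, {
    rs <- numeric(n_splits)
    nw <- integer(n_splits)
    for (s in seq_len(n_splits)) {
      half1 <- sample(children, length(children) %/% 2)
      means <- eligible |>
        dplyr::mutate(half = ifelse(.data$child_id %in% half1, "h1", "h2")) |>
        dplyr::group_by(.data$word, .data$half) |>
        dplyr::summarise(m = mean(.data$first_age_months),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "half", values_from = "m") |>
        dplyr::filter(!is.na(.data$h1), !is.na(.data$h2))
      nw[s] <- nrow(means)
      rs[s] <- if (nrow(means) >= 3) {
        stats::cor(means$h1, means$h2)
      } else {
        NA_real_
      }
    }
  })
  if (all(is.na(rs))) {
    stop("fewer than 3 words shared between halves in every split",
         call. = FALSE)
  }
  list(split_half_r = mean(rs, na.rm = TRUE), r_per_split = rs,
       n_words_per_split = nw, n_splits = as.integer(n_splits),
       seed = as.integer(seed))
}

#' Reliability report for one corpus AoA variant
#'
#' Combines ICC(2,k) (complete-row path; only defined for k >= 2
#' variants) and split-half reliability into one report.
#'
#' @param first_occ First-occurrence table.
#' @param k Variant threshold (1, 6, 12, ...).
#' @param n_splits Splits for the split-half analysis.
#' @param seed Integer seed.
#' @return List with `variant`, `icc2k`, `split_half_r`, `n_words_used`,
#'   `n_splits`, `seed`.
#' @export
reliability_report <- function(first_occ, k, n_splits = 100L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  icc <- NA_real_
  n_used <- 0L
  if (k >= 2) {
    m <- rating_matrix(first_occ, min_children = k)
    complete <- m[stats::complete.cases(m), , drop = FALSE]
    n_used <- nrow(complete)
    if (n_used >= 2) icc <- icc2k(m)
  }
  sh <- split_half(first_occ, min_children = k, n_splits = n_splits,
                   seed = seed)
  list(variant = as.integer(k), icc2k = icc,
       split_half_r = sh$split_half_r,
       n_words_used = if (k >= 2) n_used else max(sh$n_words_per_split),
       n_splits = as.integer(n_splits), seed = as.integer(seed))
}
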