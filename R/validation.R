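# Validation battery: correlation matrices, standardized regressions with
# VIF, and repeated k-fold cross-validation.

#' Complete-case correlation matrix
#'
#' Listwise-deletion correlations among the requested variables: rows with
#' any missing value on the variables are dropped before computing the
#' matrix, so every coefficient is based on the same word set.
#'
#' @param table Word-keyed norm table.
#' @param variables Character vector of column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `variables`, `r` (symmetric matrix), `n`
#'   (complete-case rows), `method`.
#' @export
correlation_matrix <- function(table, variables,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dat <- complete_word_set(table, variables)[variables]
  if (nrow(dat) < 3) stop("fewer than 3 complete-case rows", call. = FALSE)
  const <- vapply(dat, function(x) stats::sd(x) == 0, logical(1))
  r <- suppressWarnings(stats::cor(as.matrix(dat), method = method))
  if (any(const)) {
    warning("constant variable(s): ",
            paste(variables[const], collapse = ", "), call. = FALSE)
    diag(r) <- 1
  }
  list(variables = variables, r = r, n = nrow(dat), method = method)
}

#' Standardized multiple regression with VIF
#'
#' All variables are z-scored on the analysis rows, then an OLS model of
#' the outcome on the predictors is fit; coefficients are therefore
#' standardized betas.  Two-sided p-values come from the usual t
#' statistics.  The variance inflation factor of predictor j is
#' 1 / (1 - R2_j), where R2_j is from regressing predictor j on the other
#' predictors; with a single predictor VIF = 1 by definition.
#'
#' @param table Word-keyed norm table.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @return List with `outcome`, `predictors`, `beta_std`, `p_value`,
#'   `r2`, `r2_adj`, `vif`, `n`, and the fitted `lm` object (`fit`).
#' @export
standardized_regression <- function(table, outcome, predictors) {
  vars <- c(outcome, predictors)
  dat <- complete_word_set(table, vars)[vars]
  if (nrow(dat) < length(predictors) + 3) {
    stop("too few complete cases for the requested model", call. = FALSE)
  }
  z <- as.data.frame(lapply(dat, function(x) as.numeric(scale(x))))
  names(z) <- vars
  # guard against perfect collinearity before lm silently drops a column
  x <- as.matrix(z[predictors])
  if (length(predictors) > 1) {
    qrx <- qr(cbind(1, x))
    if (qrx$rank < ncol(x) + 1) {
      bad <- predictors[qrx$pivot[seq(qrx$rank + 1, ncol(x) + 1)] - 1]
      stop("perfectly collinear predictor(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  form <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(form, data = z)
  sm <- summary(fit)
  coefs <- sm$coefficients[predictors, , drop = FALSE]
  vif <- if (length(predictors) == 1) {
    stats::setNames(1, predictors)
  } else {
    vapply(predictors, function(p) {
      r2j <- summary(stats::lm(stats::reformulate(setdiff(predictors, p),
                                                  response = p),
                               data = z))$r.squared
      1 / (1 - r2j)
    }, numeric(1))
  }
  list(outcome = outcome, predictors = predictors,
       beta_std = stats::setNames(coefs[, "Estimate"], predictors),
       p_value = stats::setNames(coefs[, "Pr(>|t|)"], predictors),
       r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
       vif = vif, n = nrow(dat), fit = fit)
}

#' Repeated k-fold cross-validated RMSE
#'
#' Repeated k-fold cross-validation of the standardized regression.  The
#' z-scoring is refit inside each training fold and applied to the held
#' out fold, so no information leaks from test to train.  The outcome is
#' standardized as well, putting the RMSE on the standardized scale: a
#' model with no predictive value has expected RMSE 1.
#'
#' @param table Word-keyed norm table.
#' @param outcome Outcome column name.
#' @param predictors Predictor column names.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 4).
#' @param seed Integer seed (mandatory).
#' @return List with `cv_rmse` (mean out-of-fold RMSE over folds x
#'   repeats), `rmse_per_fold`, `folds`, `repeats`, `seed`.
#' @export
cross_validate <- function(table, outcome, predictors, folds = 5L,
                           repeats = 4L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  vars <- c(outcome, predictors)
  dat <- complete_word_set(table, vars)[vars]
  n <- nrow(dat)
  if (n < folds) stop("fewer complete cases than folds", call. = FALSE)
  form <- stats::reformulate(predictors, response = outcome)
  rmses <- numeric(0)
  withr::with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      for (f in seq_len(folds)) {
        train <- dat[fold_id != f, , drop = FALSE]
        test <- dat[fold_id == f, , drop = FALSE]
        if (nrow(test) < 2 || nrow(train) < 2) {
          stop("fold with fewer than 2 rows", call. = FALSE)
        }
        mu <- vapply(train, mean, numeric(1))
        sdv <- vapply(train, stats::sd, numeric(1))
        sdv[sdv == 0] <- 1
        ztr <- as.data.frame(Map(function(x, m, s) (x - m) / s,
                                 train, mu, sdv))
        zte <- as.data.frame(Map(function(x, m, s) (x - m) / s,
                                 test, mu, sdv))
        fit <- stats::lm(form, data = ztr)
        pred <- stats::predict(fit, newdata = zte)
        rmses <- c(rmses, sqrt(mean((zte[[outcome]] - pred)^2)))
      }
    }
  })
  list(cv_rmse = mean(rmses), rmse_per_fold = rmses,
       folds = as.integer(folds), repeats = as.integer(repeats),
       seed = as.integer(seed))
}

#' Regression table in long form
#'
#' Flattens a [standardized_regression()] result (plus optional CV RMSE)
#' into a tidy coefficient table for CSV export.
#'
#' @param reg Result of [standardized_regression()].
#' @param cv Optional result of [cross_validate()].
#' @return Tibble with one row per predictor and model-level columns
#'   repeated.
#' @export
regression_table <- function(reg, cv = NULL) {
  tibble::tibble(
    outcome = reg$outcome,
    predictor = reg$predictors,
    beta_std = unname(reg$beta_std),
    p_value = unname(reg$p_value),
    vif = unname(reg$vif),
    r2 = reg$r2,
    r2_adj = reg$r2_adj,
    n = reg$n,
    cv_rmse = if (is.null(cv)) NA_real_ else cv$cv_rmse)
}
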