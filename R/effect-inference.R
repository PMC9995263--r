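#' Prediction-outcome correlation
#'
#' The effect size of a multivariate BWAS model: the Pearson correlation
#' between model predictions and observed outcomes. Constant inputs raise an
#' error rather than silently returning 0 or `NA`.
#'
#' @param predictions,outcomes Numeric vectors of equal length (at least 3).
#' @return A number in `[-1, 1]`.
#' @export
prediction_outcome_r <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes)) {
    abort("`predictions` and `outcomes` must have equal length.",
          class = "bwasrep_size_error")
  }
  if (length(predictions) < 3) {
    abort("need at least 3 pairs to correlate.", class = "bwasrep_size_error")
  }
  if (sd(predictions) == 0 || sd(outcomes) == 0) {
    abort("correlation undefined: one of the vectors is constant.",
          class = "bwasrep_numeric_error")
  }
  cor(predictions, outcomes)
}

#' P-value of a Pearson correlation
#'
#' Exact t-transform test: `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t distribution with `n - 2` degrees of freedom. The one-sided version tests
#' `r > 0`. At `|r| = 1` the p-value is exactly 0 (a boundary case).
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param n Sample size(s), at least 4.
#' @param sidedness `"two_sided"` (default) or `"one_sided"`.
#' @return P-value(s) in `[0, 1]`.
#' @examples
#' r_p_value(0.0882, 495)            # just under 0.05
#' critical_r(495, alpha = 0.05)     # ~0.088
#' @export
r_p_value <- function(r, n, sidedness = c("two_sided", "one_sided")) {
  sidedness <- sidedness_match(sidedness)
  if (any(abs(r) > 1)) {
    abort("`r` must lie in [-1, 1].", class = "bwasrep_config_error")
  }
  if (any(n < 4)) {
    abort("`n` must be at least 4.", class = "bwasrep_size_error")
  }
  tstat <- ifelse(abs(r) == 1, Inf * sign(r),
                  r * sqrt((n - 2) / (1 - r^2)))
  if (sidedness == "two_sided") {
    2 * pt(-abs(tstat), df = n - 2)
  } else {
    pt(tstat, df = n - 2, lower.tail = FALSE)
  }
}

#' Critical correlation for a given significance level
#'
#' The smallest nonnegative `r` whose p-value reaches `alpha` at sample size
#' `n`; the inverse of [r_p_value()], closed form
#' `r = t / sqrt(n - 2 + t^2)` with `t` the relevant t quantile. Decreases
#' monotonically in `n` (as roughly `z / sqrt(n)` for large `n`).
#'
#' @param n Sample size(s), at least 4.
#' @param alpha Significance level in `(0, 1)`.
#' @inheritParams r_p_value
#' @return Critical correlation(s) in `(0, 1)`.
#' @export
critical_r <- function(n, alpha = 0.05, sidedness = c("two_sided", "one_sided")) {
  sidedness <- sidedness_match(sidedness)
  if (any(n < 4)) {
    abort("`n` must be at least 4.", class = "bwasrep_size_error")
  }
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  p_tail <- if (sidedness == "two_sided") alpha / 2 else alpha
  tcrit <- qt(1 - p_tail, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Fisher-z confidence interval for a correlation
#'
#' Parametric interval `tanh(atanh(r) +/- z / sqrt(n - 3))`, symmetric on the
#' Fisher-z scale; it always contains `r` and narrows as `n` grows.
#'
#' @param r Correlation with `|r| < 1`.
#' @param n Sample size, at least 4.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (any(abs(r) >= 1)) {
    abort("|r| = 1 gives a degenerate interval.",
          class = "bwasrep_numeric_error")
  }
  if (any(n < 4)) {
    abort("`n` must be at least 4.", class = "bwasrep_size_error")
  }
  assert_scalar_number(level, "level", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  z <- qnorm((1 + level) / 2)
  half <- z / sqrt(n - 3)
  c(low = tanh(atanh(r) - half), high = tanh(atanh(r) + half))
}

#' Build an effect-size estimate from predictions
#'
#' Wraps the prediction-outcome correlation with its sample size, test
#' p-value and parametric Fisher-z interval, tagged by estimation method
#' (`"cv"` for pooled out-of-fold predictions, `"in_sample"` for train-set
#' predictions).
#'
#' @param predictions,outcomes Numeric vectors of equal length.
#' @param method `"cv"` or `"in_sample"`.
#' @param k_folds Number of folds behind CV predictions (recorded; `NA` for
#'   in-sample estimates).
#' @param sidedness Test sidedness, see [r_p_value()].
#' @param level Confidence level of the interval.
#' @return One-row tibble of class `effect_estimate` with columns `r`, `n`,
#'   `method`, `p_value`, `sidedness`, `ci_low`, `ci_high`, `k_folds`.
#' @export
estimate_effect <- function(predictions, outcomes,
                            method = c("cv", "in_sample"), k_folds = NA,
                            sidedness = c("two_sided", "one_sided"),
                            level = 0.95) {
  method <- match.arg(method)
  sidedness <- sidedness_match(sidedness)
  r <- prediction_outcome_r(predictions, outcomes)
  n <- length(outcomes)
  ci <- if (abs(r) < 1) fisher_ci(r, n, level) else c(low = r, high = r)
  out <- tibble::tibble(
    r = r, n = n, method = method,
    p_value = r_p_value(r, n, sidedness),
    sidedness = sidedness,
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    k_folds = as.integer(k_folds)
  )
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Permutation null distribution of an effect-size estimator
#'
#' For each sample size in `n_grid`: subsample that many rows, permute the
#' outcome relative to the features, and compute the chosen estimator's
#' prediction-outcome correlation; repeated `n_permutations` times. The
#' cross-validated estimator is unbiased under the null (mean null r
#' indistinguishable from 0), whereas the in-sample estimator of a flexible
#' model is systematically positive — the overfitting bias this summary
#' makes visible.
#'
#' @inheritParams cv_predictions
#' @param estimator `"cv"` (out-of-fold predictions) or `"in_sample"` (fit and
#'   evaluate on the same rows).
#' @param n_grid Integer vector of subsample sizes, each `<= nrow(data)`.
#' @param n_permutations Number of permutations per grid point (at least 20).
#' @return A tibble of class `bwas_null`, one row per grid size, with columns
#'   `estimator`, `n`, `mean_r`, `lo`, `hi` (2.5/97.5 permutation
#'   percentiles), `n_perm`; the individual draws are in `attr(, "draws")`.
#' @export
permutation_null <- function(data, spec = model_spec("ridge"),
                             estimator = c("cv", "in_sample"),
                             n_grid = 200, n_permutations = 100,
                             k_folds = 10, seed = 1L,
                             outcome = "outcome", id_col = "sample_id") {
  estimator <- match.arg(estimator)
  assert_scalar_number(n_permutations, "n_permutations", lower = 20,
                       integerish = TRUE)
  parts <- bwas_xy(data, outcome = outcome, id_col = id_col)
  n_total <- nrow(parts$x)
  if (any(n_grid > n_total)) {
    abort(sprintf("grid sizes must not exceed the dataset size (%d).", n_total),
          class = "bwasrep_size_error")
  }
  if (any(n_grid < 8)) {
    abort("grid sizes below 8 are too small for a stable null.",
          class = "bwasrep_size_error")
  }

  draws <- purrr::map_dfr(n_grid, function(n) {
    rs <- vapply(seq_len(n_permutations), function(i) {
      s <- derive_seed(seed, n, i)
      idx <- with_seed(s, sample.int(n_total, n))
      x <- parts$x[idx, , drop = FALSE]
      yperm <- with_seed(derive_seed(s, 7L), sample(parts$y[idx]))
      if (estimator == "in_sample") {
        fit <- fit_core(spec, x, yperm)
        prediction_outcome_r(predict(fit, x), yperm)
      } else {
        cv <- cv_predictions(x, spec, k_folds = k_folds, seed = s, y = yperm)
        prediction_outcome_r(cv$predicted, cv$observed)
      }
    }, numeric(1))
    tibble::tibble(estimator = estimator, n = n,
                   perm = seq_len(n_permutations), r = rs)
  })

  out <- draws |>
    dplyr::group_by(.data$estimator, .data$n) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      lo = unname(quantile(.data$r, 0.025)),
      hi = unname(quantile(.data$r, 0.975)),
      n_perm = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "draws") <- draws
  class(out) <- c("bwas_null", class(out))
  out
}
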