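#' Analytic power of a correlation test (Fisher-z approximation)
#'
#' Probability that a sample Pearson correlation from `n` draws at true
#' correlation `rho` is significant at level `alpha`:
#' `pnorm(atanh(rho) * sqrt(n - 3) - z)`, with `z` the `1 - alpha/2` (two
#' sided; the opposite-tail mass is negligible for `rho > 0`) or `1 - alpha`
#' (one sided) normal quantile. Monotone increasing in both `n` and `rho`.
#'
#' `rho^2` is the fraction of outcome variance explained, so e.g.
#' `rho = 0.1` corresponds to a model explaining 1% of variance.
#'
#' @param rho True correlation in `(0, 1)`.
#' @param n Sample size(s), at least 4.
#' @param alpha Significance level (default 0.05).
#' @param sidedness `"two_sided"` (default) or `"one_sided"`.
#' @return Power value(s) in `(0, 1)`.
#' @examples
#' power_at_n(0.1, 783)       # ~0.80
#' required_n(0.1)            # 783
#' @export
power_at_n <- function(rho, n, alpha = 0.05,
                       sidedness = c("two_sided", "one_sided")) {
  sidedness <- sidedness_match(sidedness)
  assert_scalar_number(rho, "rho", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  if (any(n < 4)) {
    abort("`n` must be at least 4.", class = "bwasrep_size_error")
  }
  z <- if (sidedness == "two_sided") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  pnorm(atanh(rho) * sqrt(n - 3) - z)
}

#' Minimal sample size for target power of a correlation test
#'
#' Inverts the Fisher-z power formula,
#' `n = ((z_alpha + z_power) / atanh(rho))^2 + 3`, then adjusts by direct
#' evaluation of [power_at_n()] to guarantee the returned `n` is minimal:
#' `power_at_n(rho, n) >= target_power` and
#' `power_at_n(rho, n - 1) < target_power`.
#'
#' @inheritParams power_at_n
#' @param target_power Required power in `(0, 1)` (default 0.8).
#' @param n_cap Upper bound on the search (default `1e8`); effects so small
#'   that the requirement exceeds the cap raise an error.
#' @return Integer sample size.
#' @export
required_n <- function(rho, target_power = 0.8, alpha = 0.05,
                       sidedness = c("two_sided", "one_sided"),
                       n_cap = 1e8) {
  sidedness <- sidedness_match(sidedness)
  assert_scalar_number(rho, "rho", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  assert_scalar_number(target_power, "target_power", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  z_a <- if (sidedness == "two_sided") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  z_p <- qnorm(target_power)
  n0 <- ceiling(((z_a + z_p) / atanh(rho))^2 + 3)
  if (n0 > n_cap) {
    abort(sprintf("required n exceeds the cap of %g.", n_cap),
          class = "bwasrep_range_error")
  }
  n0 <- max(n0, 4)
  # refine to guarantee minimality despite ceiling/rounding
  while (n0 > 4 && power_at_n(rho, n0 - 1, alpha, sidedness) >= target_power) {
    n0 <- n0 - 1
  }
  while (power_at_n(rho, n0, alpha, sidedness) < target_power) {
    n0 <- n0 + 1
    if (n0 > n_cap) {
      abort(sprintf("required n exceeds the cap of %g.", n_cap),
            class = "bwasrep_range_error")
    }
  }
  as.integer(n0)
}

#' Power table over a grid of effect sizes and sample sizes
#'
#' @param rho Vector of true correlations in `(0, 1)`.
#' @param n Vector of sample sizes.
#' @inheritParams power_at_n
#' @return A tibble of class `power_curve` with one row per (`rho`, `n`) cell
#'   and a `power` column.
#' @export
power_curve <- function(rho, n, alpha = 0.05,
                        sidedness = c("two_sided", "one_sided")) {
  sidedness <- sidedness_match(sidedness)
  if (length(rho) < 1 || length(n) < 1) {
    abort("`rho` and `n` must be non-empty.", class = "bwasrep_config_error")
  }
  out <- tidyr::expand_grid(rho = rho, n = n)
  out$power <- purrr::map2_dbl(out$rho, out$n,
                               ~power_at_n(.x, .y, alpha, sidedness))
  out$alpha <- alpha
  class(out) <- c("power_curve", class(out))
  out
}

#' Monte-Carlo rejection rate of the correlation test
#'
#' Simulation counterpart of [power_at_n()]: draws bivariate normal samples
#' at true correlation `rho` and reports the fraction in which the
#' t-transform test rejects at `alpha`. Used as an independent check on the
#' closed-form approximation.
#'
#' @inheritParams power_at_n
#' @param n_sim Number of simulated samples (default 10000).
#' @param seed Integer seed.
#' @return Rejection fraction in `[0, 1]`.
#' @export
simulate_power <- function(rho, n, alpha = 0.05, n_sim = 10000, seed = 1L,
                           sidedness = c("two_sided", "one_sided")) {
  sidedness <- sidedness_match(sidedness)
  assert_scalar_number(rho, "rho", lower = 0, upper = 1, open_upper = TRUE)
  assert_scalar_number(n, "n", lower = 4, integerish = TRUE)
  assert_scalar_number(n_sim, "n_sim", lower = 1, integerish = TRUE)
  crit <- critical_r(n, alpha, sidedness)
  rs <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      cor(x, y)
    }, numeric(1))
  })
  if (sidedness == "two_sided") mean(abs(rs) >= crit) else mean(rs >= crit)
}
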