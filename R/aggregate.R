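#' Aggregate benchmark records into replicability metrics
#'
#' Per grid sample size, computes the metrics of the replicability analysis:
#'
#' * `mean_inflation_insample` — mean of `r_disc_insample - r_rep`, the
#'   inflation of the naive (non-cross-validated) discovery estimate over the
#'   replication effect.
#' * `mean_inflation_cv` — mean of `r_disc_cv - r_rep`; near zero when
#'   cross-validation removes the overfitting bias.
#' * `power` — fraction of replicates that are discovery-positive
#'   (`p_disc_cv <= alpha` and `r_disc_cv > 0`).
#' * `p_rep` — out-of-sample replication probability: among
#'   discovery-positive replicates, the fraction that are also
#'   replication-positive (`p_rep_value <= alpha` and `r_rep > 0`). `NA` when
#'   no replicate is discovery-positive (never a silent 0).
#' * `conditional_inflation` — mean of `r_disc_cv - r_rep` over the
#'   conditioning subset (default: discovery-positive replicates), the
#'   winner's-curse / publication-bias inflation.
#'
#' Uncertainty bounds `lo`/`hi` are 2.5/97.5 percentile intervals from a
#' bootstrap over replicates within each grid size.
#'
#' @param records A `bwas_benchmark` tibble from [run_benchmark()], or any
#'   data frame with its columns.
#' @param alpha Significance level; defaults to the benchmark configuration's.
#' @param conditioning Conditioning subset for `conditional_inflation`;
#'   defaults to the configuration's (see [benchmark_config()]).
#' @param n_boot Bootstrap resamples for the percentile intervals
#'   (default 1000).
#' @param seed Seed of the interval bootstrap.
#' @return A tibble of class `benchmark_table`, one row per grid size and
#'   metric: `n`, `metric`, `value`, `lo`, `hi`, `subset_n` (number of
#'   replicates the value is computed from).
#' @export
aggregate_benchmark <- function(records, alpha = NULL, conditioning = NULL,
                                n_boot = 1000, seed = 1L) {
  cfg <- attr(records, "config")
  alpha <- alpha %||% cfg$alpha %||% 0.05
  conditioning <- conditioning %||% cfg$conditioning %||% "discovery_significant"
  conditioning <- match.arg(conditioning,
                            c("discovery_significant", "none",
                              "replication_significant", "both"))
  needed <- c("n", "r_disc_insample", "r_disc_cv", "p_disc_cv",
              "r_rep", "p_rep_value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack columns: ", toString(missing_cols)),
          class = "bwasrep_config_error")
  }

  metric_row <- function(df) {
    disc_pos <- df$p_disc_cv <= alpha & df$r_disc_cv > 0
    rep_pos <- df$p_rep_value <= alpha & df$r_rep > 0
    cond <- switch(conditioning,
      none = rep(TRUE, nrow(df)),
      discovery_significant = disc_pos,
      replication_significant = rep_pos,
      both = disc_pos & rep_pos
    )
    tibble::tibble(
      metric = c("mean_inflation_insample", "mean_inflation_cv", "power",
                 "p_rep", "conditional_inflation"),
      value = c(
        mean(df$r_disc_insample - df$r_rep),
        mean(df$r_disc_cv - df$r_rep),
        mean(disc_pos),
        if (any(disc_pos)) mean(rep_pos[disc_pos]) else NA_real_,
        if (any(cond)) mean((df$r_disc_cv - df$r_rep)[cond]) else NA_real_
      ),
      subset_n = c(nrow(df), nrow(df), nrow(df), sum(disc_pos), sum(cond))
    )
  }

  out <- records |>
    dplyr::group_by(.data$n) |>
    dplyr::group_modify(function(df, key) {
      point <- metric_row(df)
      boot <- with_seed(derive_seed(seed, key$n), {
        vals <- replicate(n_boot, {
          metric_row(df[sample.int(nrow(df), replace = TRUE), ])$value
        })
        matrix(vals, nrow = nrow(point))
      })
      point$lo <- apply(boot, 1, function(v) {
        if (all(is.na(v))) NA_real_ else unname(quantile(v, 0.025, na.rm = TRUE))
      })
      point$hi <- apply(boot, 1, function(v) {
        if (all(is.na(v))) NA_real_ else unname(quantile(v, 0.975, na.rm = TRUE))
      })
      point[, c("metric", "value", "lo", "hi", "subset_n")]
    }) |>
    dplyr::ungroup()
  attr(out, "alpha") <- alpha
  attr(out, "conditioning") <- conditioning
  class(out) <- c("benchmark_table", class(out))
  out
}

#' Smallest grid sample size reaching a metric threshold
#'
#' Scans the benchmark table in increasing `n` and returns the first grid
#' size whose metric value meets the threshold — no interpolation between
#' grid points. When no grid size qualifies, returns `Inf` with a `label`
#' attribute of the form `">500"`, the "bar with arrow" sentinel meaning the
#' requirement exceeds the largest size tested. A non-monotone metric still
#' returns the first crossing, with a warning.
#'
#' @param table A `benchmark_table` from [aggregate_benchmark()] (or any data
#'   frame with columns `n`, `metric`, `value`).
#' @param metric `"power"` or `"p_rep"`.
#' @param threshold Required metric level (default 0.8).
#' @return Integer sample size, or `Inf` (above-grid sentinel; see `label`
#'   attribute).
#' @examples
#' tab <- tibble::tibble(n = c(75, 150, 300, 500), metric = "power",
#'                       value = c(0.4, 0.7, 0.85, 0.95))
#' min_n(tab, "power", 0.8)  # 300
#' @export
min_n <- function(table, metric = c("power", "p_rep"), threshold = 0.8) {
  metric <- match.arg(metric)
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  rows <- table[table$metric == metric, c("n", "value")]
  if (nrow(rows) < 2) {
    abort("the table must cover at least 2 grid sizes for this metric.",
          class = "bwasrep_config_error")
  }
  rows <- rows[order(rows$n), ]
  ok <- !is.na(rows$value) & rows$value >= threshold
  vals_ok <- rows$value[!is.na(rows$value)]
  if (any(diff(vals_ok) < 0)) {
    warn(sprintf("`%s` is not monotone in n; returning the first crossing.",
                 metric))
  }
  if (!any(ok)) {
    return(structure(Inf, label = sprintf(">%d", max(rows$n))))
  }
  n_star <- as.integer(rows$n[which(ok)[1]])
  structure(n_star, label = as.character(n_star))
}
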