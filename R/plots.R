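# ggplot2 displays for the main result types

#' Plot benchmark records: discovery vs replication effect sizes
#'
#' Scatter of discovery-sample effect sizes (in-sample and cross-validated)
#' against the replication effect size, one point per bootstrap replicate,
#' with the identity line and the critical-r thresholds at the configured
#' alpha. Points on the identity line indicate unbiased discovery estimates.
#'
#' @param object A `bwas_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bwas_benchmark
#' @export
autoplot.bwas_benchmark <- function(object, ...) {
  cfg <- attr(object, "config")
  alpha <- cfg$alpha %||% 0.05
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("r_disc_insample", "r_disc_cv"),
    names_to = "estimator", values_to = "r_discovery"
  )
  long$estimator <- dplyr::recode(long$estimator,
                                  r_disc_insample = "in-sample (no CV)",
                                  r_disc_cv = "cross-validated")
  thresholds <- tibble::tibble(n = unique(long$n),
                               crit = critical_r(unique(long$n), alpha))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r_discovery, y = .data$r_rep,
                                     colour = factor(.data$n))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(data = thresholds,
                        ggplot2::aes(xintercept = .data$crit),
                        linetype = 3, colour = "grey60") +
    ggplot2::facet_wrap(~estimator) +
    ggplot2::labs(x = "discovery effect size (r)",
                  y = "replication effect size (r)",
                  colour = "n") +
    ggplot2::theme_minimal()
}

#' Plot aggregated replicability metrics against sample size
#'
#' @param object A `benchmark_table` from [aggregate_benchmark()].
#' @param metrics Metrics to show (default power and replication
#'   probability).
#' @param threshold Horizontal reference level (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_table
#' @export
autoplot.benchmark_table <- function(object, metrics = c("power", "p_rep"),
                                     threshold = 0.8, ...) {
  df <- object[object$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 3,
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$metric), alpha = 0.15,
                         colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size (per discovery/replication half)",
                  y = "value", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution summary
#'
#' Mean null effect size with 2.5/97.5 permutation percentiles per sample
#' size; an unbiased estimator stays flat at zero, an overfitting in-sample
#' estimator does not.
#'
#' @param object A `bwas_null` from [permutation_null()] (several can be
#'   row-bound first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bwas_null
#' @export
autoplot.bwas_null <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$mean_r,
                                       colour = .data$estimator,
                                       fill = .data$estimator)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size", y = "null effect size (r)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot analytic power curves
#'
#' @param object A `power_curve` from [power_curve()].
#' @param target Horizontal reference power (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, target = 0.8, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$power,
                                       colour = factor(.data$rho))) +
    ggplot2::geom_hline(yintercept = target, linetype = 3,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample size", y = "power",
                  colour = expression(rho)) +
    ggplot2::theme_minimal()
}
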