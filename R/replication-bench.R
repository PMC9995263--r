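#' Configuration of a discovery/replication bootstrap benchmark
#'
#' Describes the core replicability experiment: at each sample size in
#' `n_grid`, `n_bootstrap` pairs of disjoint discovery and replication
#' subsamples are drawn, a model is trained on the discovery half, and
#' in-sample, cross-validated and replication effect sizes are recorded.
#'
#' @param n_grid Increasing vector of subsample sizes. The default brackets
#'   the 75-500 range typical of moderately sized BWAS plus smaller sizes
#'   where variability dominates.
#' @param n_bootstrap Number of replicate pairs per grid size (default 100).
#' @param alpha Significance level used for positivity calls (default 0.05).
#' @param model A [model_spec()].
#' @param k_folds Folds for the cross-validated discovery estimate.
#' @param conditioning Subset over which conditional (publication-bias)
#'   inflation is averaged: `"discovery_significant"` (default; the standard
#'   winner's-curse construction), `"replication_significant"`, `"both"`, or
#'   `"none"`.
#' @param sidedness Sidedness of the significance tests.
#' @param seed Integer master seed; every replicate derives its own seed from
#'   it, so results are independent of execution order.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_grid = c(25, 50, 75, 100, 150, 200, 300, 400, 500),
                             n_bootstrap = 100,
                             alpha = 0.05,
                             model = model_spec("ridge"),
                             k_folds = 10,
                             conditioning = c("discovery_significant", "none",
                                              "replication_significant", "both"),
                             sidedness = c("two_sided", "one_sided"),
                             seed = 1L) {
  conditioning <- match.arg(conditioning)
  sidedness <- sidedness_match(sidedness)
  if (length(n_grid) < 1 || any(diff(n_grid) <= 0)) {
    abort("`n_grid` must be strictly increasing.",
          class = "bwasrep_config_error")
  }
  assert_scalar_number(n_bootstrap, "n_bootstrap", lower = 1,
                       integerish = TRUE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  assert_scalar_number(k_folds, "k_folds", lower = 2, integerish = TRUE)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  stopifnot(inherits(model, "model_spec"))
  structure(
    list(
      n_grid = as.integer(n_grid),
      n_bootstrap = as.integer(n_bootstrap),
      alpha = alpha,
      model = model,
      k_folds = as.integer(k_folds),
      conditioning = conditioning,
      sidedness = sidedness,
      seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

#' Draw disjoint discovery and replication subsamples
#'
#' Samples `2 * n` rows without replacement and splits them into two disjoint
#' subsets of size `n`. Disjointness makes the replication half a genuinely
#' independent sample for the discovery-trained model.
#'
#' @param data A data frame of samples.
#' @param n Size of each subset; `2 * n` must not exceed `nrow(data)`.
#' @param seed Integer seed.
#' @return A list with tibbles `discovery` and `replication`.
#' @export
draw_pair <- function(data, n, seed) {
  assert_scalar_number(n, "n", lower = 2, integerish = TRUE)
  n <- as.integer(n)
  if (2L * n > nrow(data)) {
    abort(sprintf("2 * n = %d exceeds the available sample size %d.",
                  2L * n, nrow(data)),
          class = "bwasrep_size_error")
  }
  idx <- with_seed(seed, sample.int(nrow(data), 2L * n))
  list(
    discovery = data[idx[seq_len(n)], , drop = FALSE],
    replication = data[idx[n + seq_len(n)], , drop = FALSE]
  )
}

#' Run a single discovery/replication replicate
#'
#' Draws one disjoint pair, trains the model on the discovery subset and
#' records three effect sizes: (i) the non-cross-validated in-sample
#' correlation (fit and evaluate on all discovery rows), (ii) the
#' cross-validated correlation from pooled out-of-fold predictions within
#' discovery, and (iii) the replication correlation of the single
#' discovery-trained model applied unchanged to the replication subset.
#'
#' @inheritParams draw_pair
#' @param spec A [model_spec()].
#' @param k_folds Folds for the CV estimate.
#' @param alpha Significance level (recorded only; positivity calls are made
#'   in [aggregate_benchmark()]).
#' @param sidedness Sidedness of the recorded p-values.
#' @param outcome,id_col Column roles.
#' @return One-row tibble with `n`, `r_disc_insample`, `r_disc_cv`,
#'   `p_disc_cv`, `r_rep`, `p_rep_value`, `seed_used`; or `NULL` if a subset
#'   had a constant outcome (invalid replicate).
#' @export
run_replicate <- function(data, n, spec = model_spec("ridge"), k_folds = 10,
                          alpha = 0.05, seed = 1L,
                          sidedness = "two_sided",
                          outcome = "outcome", id_col = "sample_id") {
  pair <- draw_pair(data, n, seed)
  res <- tryCatch({
    disc <- bwas_xy(pair$discovery, outcome = outcome, id_col = id_col)
    repl <- bwas_xy(pair$replication, outcome = outcome, id_col = id_col)
    fit_full <- fit_core(spec, disc$x, disc$y)
    r_in <- prediction_outcome_r(predict(fit_full, disc$x), disc$y)
    cv <- cv_predictions(disc$x, spec, k_folds = k_folds,
                         seed = derive_seed(seed, 13L), y = disc$y)
    r_cv <- prediction_outcome_r(cv$predicted, cv$observed)
    pred_rep <- predict(fit_full, repl$x)
    r_rep <- prediction_outcome_r(pred_rep, repl$y)
    tibble::tibble(
      n = as.integer(n),
      r_disc_insample = r_in,
      r_disc_cv = r_cv,
      p_disc_cv = r_p_value(r_cv, n, sidedness),
      r_rep = r_rep,
      p_rep_value = r_p_value(r_rep, n, sidedness),
      seed_used = as.integer(seed)
    )
  }, bwasrep_fit_error = function(e) NULL,
     bwasrep_numeric_error = function(e) NULL)
  res
}

#' Run the full discovery/replication bootstrap benchmark
#'
#' Executes [run_replicate()] `n_bootstrap` times at every grid size of the
#' configuration. Each replicate's seed is derived deterministically from the
#' master seed and the pair (grid size, replicate index), so the records are
#' reproducible, order-insensitive, and extending `n_bootstrap` leaves earlier
#' replicates unchanged. Invalid replicates (constant outcome in a subset)
#' are excluded and counted; the run aborts if more than 10% are invalid.
#'
#' @param data A data frame of samples (e.g. from [simulate_bwas_data()]).
#' @param config A [benchmark_config()].
#' @param outcome,id_col Column roles.
#' @return A tibble of class `bwas_benchmark`: one row per valid replicate
#'   with a `replicate` index column, the configuration in
#'   `attr(, "config")` and the invalid count in `attr(, "n_invalid")`.
#' @examples
#' ds <- simulate_bwas_data(300, 40, rho_true = 0.5, seed = 1)
#' cfg <- benchmark_config(n_grid = c(50, 100), n_bootstrap = 5, seed = 1)
#' bench <- run_benchmark(ds, cfg)
#' aggregate_benchmark(bench)
#' @export
run_benchmark <- function(data, config = benchmark_config(),
                          outcome = "outcome", id_col = "sample_id") {
  stopifnot(inherits(config, "benchmark_config"))
  if (2L * max(config$n_grid) > nrow(data)) {
    abort(sprintf(
      "largest grid size %d needs %d samples for disjoint pairs; data has %d.",
      max(config$n_grid), 2L * max(config$n_grid), nrow(data)
    ), class = "bwasrep_size_error")
  }
  grid <- expand.grid(b = seq_len(config$n_bootstrap), n = config$n_grid)
  records <- purrr::pmap(grid, function(b, n) {
    rec <- run_replicate(
      data, n, spec = config$model, k_folds = config$k_folds,
      alpha = config$alpha, seed = derive_seed(config$seed, n, b),
      sidedness = config$sidedness, outcome = outcome, id_col = id_col
    )
    if (!is.null(rec)) rec$replicate <- as.integer(b)
    rec
  })
  n_invalid <- sum(vapply(records, is.null, logical(1)))
  if (n_invalid > 0.1 * nrow(grid)) {
    abort(sprintf("%d of %d replicates invalid (>10%%); aborting.",
                  n_invalid, nrow(grid)),
          class = "bwasrep_numeric_error")
  }
  out <- dplyr::bind_rows(records)
  out <- dplyr::relocate(out, "n", "replicate")
  attr(out, "config") <- config
  attr(out, "n_invalid") <- n_invalid
  class(out) <- c("bwas_benchmark", class(out))
  out
}

#' Cross-validated effect size on the full dataset
#'
#' @inheritParams cv_predictions
#' @return An [estimate_effect()] one-row tibble (`method = "cv"`).
#' @export
full_sample_effect <- function(data, spec = model_spec("ridge"), k_folds = 10,
                               seed = 1L, outcome = "outcome",
                               id_col = "sample_id") {
  cv <- cv_predictions(data, spec, k_folds = k_folds, seed = seed,
                       outcome = outcome, id_col = id_col)
  estimate_effect(cv$predicted, cv$observed, method = "cv", k_folds = k_folds)
}

#' @method glance bwas_benchmark
#' @export
glance.bwas_benchmark <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_records = nrow(x),
    n_grid_points = length(unique(x$n)),
    n_bootstrap = cfg$n_bootstrap,
    n_invalid = attr(x, "n_invalid") %||% 0L,
    model = cfg$model$family,
    alpha = cfg$alpha,
    seed = cfg$seed
  )
}
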