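#' Simulate a connectome-style dataset with a known multivariate effect size
#'
#' Generates a samples-by-features table that mimics the statistical structure
#' multivariate brain-wide association studies (BWAS) operate on: many
#' correlated continuous features (standing in for vectorized connectivity
#' edges) and a continuous phenotype whose *population* association with the
#' optimal linear readout of the features is exactly `rho_true`.
#'
#' Features are zero-mean unit-variance Gaussians with an equicorrelated block
#' structure: features within a block of `block_size` share pairwise
#' correlation `block_rho`, features in different blocks are independent. A
#' latent signal `f = X %*% w` is built from fixed weights on the first
#' `n_signal` features (weights drawn once from a standard normal, then scaled
#' so `f` has unit population variance) and the outcome is
#' `y = rho_true * f + sqrt(1 - rho_true^2) * e` with standard normal noise, so
#' the population correlation between the best linear predictor and `y` equals
#' `rho_true` by construction. `rho_true = 0` yields an outcome independent of
#' all features.
#'
#' @param n_samples Number of samples (rows).
#' @param n_features Number of features `p` (columns).
#' @param rho_true Population correlation between the optimal linear predictor
#'   and the outcome, in `[0, 1)`. Its square is the variance explained.
#' @param n_signal Number of leading features carrying signal (`<= p`).
#' @param block_size Features per correlated block; the last block may be
#'   smaller if `block_size` does not divide `n_features`.
#' @param block_rho Within-block feature correlation, in `[0, 1)`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A tibble of class `bwas_data` with columns `sample_id`, `outcome`
#'   and `f0001 ... f<p>`, carrying the ground truth (weights, `rho_true`, the
#'   full configuration) in the `"bwas_truth"` attribute.
#' @seealso [population_effect()], [permute_outcome()], [write_bwas_data()]
#' @examples
#' ds <- simulate_bwas_data(n_samples = 100, n_features = 20,
#'                          rho_true = 0.5, seed = 1)
#' population_effect(ds)
#' @export
simulate_bwas_data <- function(n_samples = 1200, n_features = 200,
                               rho_true = 0.3,
                               n_signal = max(1L, round(n_features / 4)),
                               block_size = 10, block_rho = 0.3,
                               seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 1, integerish = TRUE)
  assert_scalar_number(n_features, "n_features", lower = 1, integerish = TRUE)
  assert_scalar_number(rho_true, "rho_true", lower = 0, upper = 1,
                       open_upper = TRUE)
  assert_scalar_number(n_signal, "n_signal", lower = 1, upper = n_features,
                       integerish = TRUE)
  assert_scalar_number(block_size, "block_size", lower = 1, integerish = TRUE)
  assert_scalar_number(block_rho, "block_rho", lower = 0, upper = 1,
                       open_upper = TRUE)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  n <- as.integer(n_samples)
  p <- as.integer(n_features)
  block_size <- as.integer(block_size)
  n_signal <- as.integer(n_signal)

  block_of <- ceiling(seq_len(p) / block_size)
  n_blocks <- max(block_of)

  with_seed(seed, {
    g <- matrix(rnorm(n * n_blocks), n, n_blocks)
    e <- matrix(rnorm(n * p), n, p)
    x <- sqrt(block_rho) * g[, block_of, drop = FALSE] +
      sqrt(1 - block_rho) * e
    w <- c(rnorm(n_signal), rep(0, p - n_signal))
    # population Var(Xw) under the block-equicorrelated covariance
    var_f <- sum(vapply(seq_len(n_blocks), function(b) {
      wb <- w[block_of == b]
      (1 - block_rho) * sum(wb^2) + block_rho * sum(wb)^2
    }, numeric(1)))
    w <- w / sqrt(var_f)
    f <- drop(x %*% w)
    eps <- rnorm(n)
    y <- rho_true * f + sqrt(1 - rho_true^2) * eps
  })

  feat_names <- sprintf("f%04d", seq_len(p))
  out <- tibble::as_tibble(x, .name_repair = ~feat_names)
  out <- tibble::add_column(out,
    sample_id = sprintf("S%05d", seq_len(n)),
    outcome = y, .before = 1
  )
  attr(out, "bwas_truth") <- list(
    weights = stats::setNames(w, feat_names),
    rho_true = rho_true,
    config = list(
      n_samples = n, n_features = p, rho_true = rho_true,
      n_signal = n_signal, block_size = block_size,
      block_rho = block_rho, seed = as.integer(seed)
    )
  )
  class(out) <- c("bwas_data", class(out))
  out
}

#' True population effect size of a dataset or generator configuration
#'
#' Returns the population correlation between the generator's optimal linear
#' predictor and the outcome — the oracle against which cross-validated
#' estimates can be compared in parameter-recovery checks.
#'
#' @param x A `bwas_data` tibble from [simulate_bwas_data()], or a list with a
#'   `rho_true` element (a generator configuration).
#' @return A single number in `[0, 1)`.
#' @export
population_effect <- function(x) {
  if (inherits(x, "bwas_data")) {
    truth <- attr(x, "bwas_truth")
    if (is.null(truth)) {
      abort("dataset carries no ground truth (was it read from disk?).",
            class = "bwasrep_config_error")
    }
    return(truth$rho_true)
  }
  if (is.list(x) && !is.null(x$rho_true)) {
    assert_scalar_number(x$rho_true, "rho_true", lower = 0, upper = 1,
                         open_upper = TRUE)
    return(x$rho_true)
  }
  abort("`x` must be a `bwas_data` tibble or a list with `rho_true`.",
        class = "bwasrep_config_error")
}

#' Permute the outcome column of a dataset
#'
#' Shuffles the outcome relative to the features, preserving the multiset of
#' outcome values — the construction behind permutation null distributions of
#' prediction-outcome correlations.
#'
#' @param data A data frame with an outcome column.
#' @param seed Integer seed; the permutation is deterministic given the seed.
#' @param outcome Name of the outcome column.
#' @return `data` with the outcome column permuted; all other columns (and
#'   attributes) untouched.
#' @export
permute_outcome <- function(data, seed, outcome = "outcome") {
  if (!outcome %in% names(data)) {
    abort(sprintf("no column `%s` in `data`.", outcome),
          class = "bwasrep_config_error")
  }
  n <- nrow(data)
  idx <- with_seed(seed, sample.int(n))
  data[[outcome]] <- data[[outcome]][idx]
  data
}

#' Simulate node timeseries with a known partial-correlation network
#'
#' Draws timepoints from a multivariate Gaussian whose precision matrix is
#' randomly generated, sparse and diagonally dominant (hence positive
#' definite), and returns the samples together with the true
#' partial-correlation matrix implied by that precision matrix. Useful as a
#' fixture for the partial-correlation feature pipeline: the empirical
#' estimate from [partial_correlation_matrix()] converges to the returned
#' truth as the number of timepoints grows.
#'
#' @param n_nodes Number of nodes (variables).
#' @param n_timepoints Number of timepoints (rows). Values `<= n_nodes` are
#'   allowed but flagged with a warning.
#' @param precision_sparsity Fraction of off-diagonal precision entries forced
#'   to zero, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `timeseries` (`n_timepoints x n_nodes` matrix),
#'   `partial_cor` (true node-by-node partial correlations, unit diagonal) and
#'   `precision` (the generating precision matrix).
#' @export
generate_node_timeseries <- function(n_nodes, n_timepoints,
                                     precision_sparsity = 0.5, seed = 1L) {
  assert_scalar_number(n_nodes, "n_nodes", lower = 2, integerish = TRUE)
  assert_scalar_number(n_timepoints, "n_timepoints", lower = 2,
                       integerish = TRUE)
  assert_scalar_number(precision_sparsity, "precision_sparsity",
                       lower = 0, upper = 1)
  if (n_timepoints <= n_nodes) {
    warn("`n_timepoints` <= `n_nodes`: empirical partial correlations will be unstable.")
  }
  d <- as.integer(n_nodes)
  with_seed(seed, {
    omega <- matrix(0, d, d)
    up <- upper.tri(omega)
    vals <- runif(sum(up), -0.8, 0.8)
    keep <- runif(sum(up)) >= precision_sparsity
    omega[up] <- vals * keep
    omega <- omega + t(omega)
    # diagonal dominance guarantees positive definiteness
    diag(omega) <- rowSums(abs(omega)) + 1
    sigma <- solve(omega)
    ch <- chol(sigma)
    z <- matrix(rnorm(n_timepoints * d), n_timepoints, d)
    ts <- z %*% ch
  })
  pc <- precision_to_partial_cor(omega)
  list(timeseries = ts, partial_cor = pc, precision = omega)
}

# -Omega_ij / sqrt(Omega_ii * Omega_jj), unit diagonal
precision_to_partial_cor <- function(omega) {
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  diag(pc) <- 1
  pc
}

# internal: split a dataset into (id, y, X) given column roles
bwas_xy <- function(data, outcome = "outcome", id_col = "sample_id") {
  if (!outcome %in% names(data)) {
    abort(sprintf("no column `%s` in `data`.", outcome),
          class = "bwasrep_config_error")
  }
  feat_cols <- setdiff(names(data), c(outcome, id_col))
  x <- as.matrix(data[feat_cols])
  if (!is.numeric(x)) {
    abort("feature columns must all be numeric.",
          class = "bwasrep_config_error")
  }
  if (anyNA(x) || anyNA(data[[outcome]])) {
    abort("missing values are not supported.", class = "bwasrep_config_error")
  }
  list(
    ids = if (id_col %in% names(data)) data[[id_col]] else as.character(seq_len(nrow(data))),
    y = as.numeric(data[[outcome]]),
    x = x
  )
}
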