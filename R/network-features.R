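#' Partial-correlation matrix of node timeseries
#'
#' Estimates the node-by-node partial-correlation matrix (each pairwise
#' correlation conditioned on all remaining nodes) from a timepoints-by-nodes
#' matrix, via the inverse of a (optionally ridge-regularized) covariance
#' matrix: entry (i, j) is `-Omega_ij / sqrt(Omega_ii * Omega_jj)` where
#' `Omega` is the precision matrix. Regularization adds
#' `regularization * mean(diag(cov))` to the covariance diagonal before
#' inversion, which keeps the estimate defined when timepoints are scarce.
#'
#' @param samples Timepoints-by-nodes numeric matrix, at least 3 rows.
#' @param regularization Nonnegative ridge weight on the covariance diagonal
#'   (scaled by the mean diagonal). Default 0.1.
#' @return Symmetric nodes-by-nodes matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
partial_correlation_matrix <- function(samples, regularization = 0.1) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 3) {
    abort("need at least 3 timepoints.", class = "bwasrep_config_error")
  }
  assert_scalar_number(regularization, "regularization", lower = 0)
  s <- stats::cov(samples)
  if (regularization > 0) {
    s <- s + diag(regularization * mean(diag(s)), ncol(s))
  }
  omega <- tryCatch(solve(s), error = function(e) {
    abort(paste0(
      "covariance matrix is singular; supply a positive `regularization` ",
      "(e.g. 0.1)."
    ), class = "bwasrep_numeric_error")
  })
  pc <- precision_to_partial_cor(omega)
  pmin(pmax(pc, -1), 1)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Standard "netmat" vectorization: the strict upper triangle in row-major
#' order, i.e. (1,2), (1,3), ..., (1,d), (2,3), ..., (d-1,d), giving a feature
#' vector of length `d * (d - 1) / 2`.
#'
#' @param m Symmetric square numeric matrix (tolerance `1e-8`).
#' @return Numeric vector of length `d(d-1)/2`, named `e<i>_<j>`.
#' @export
vectorize_edges <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort("`m` must be symmetric (tolerance 1e-8).",
          class = "bwasrep_validation_error")
  }
  d <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-major
  out <- m[idx]
  names(out) <- sprintf("e%d_%d", idx[, 1], idx[, 2])
  out
}
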