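test_that("partial_correlation_matrix reduces to Pearson correlation for 2 nodes", {
  set.seed(1)
  ts <- matrix(rnorm(400), 200, 2)
  ts[, 2] <- ts[, 1] * 0.6 + rnorm(200) * 0.8
  pc <- partial_correlation_matrix(ts, regularization = 0)
  expect_equal(pc[1, 2], cor(ts)[1, 2], tolerance = 1e-10)
  expect_equal(diag(pc), rep(1, 2))
})

test_that("unregularized partial correlation matches the precision-matrix formula", {
  set.seed(2)
  ts <- matrix(rnorm(500 * 4), 500, 4)
  pc <- partial_correlation_matrix(ts, regularization = 0)
  omega <- solve(cov(ts))
  ref <- -omega / sqrt(tcrossprod(diag(omega)))
  diag(ref) <- 1
  expect_equal(pc, ref, tolerance = 1e-10)
  expect_true(all(abs(pc) <= 1))
})

test_that("singular covariance without regularization instructs a positive one", {
  set.seed(3)
  ts <- matrix(rnorm(5 * 10), 5, 10)  # rank-deficient covariance
  expect_error(partial_correlation_matrix(ts, regularization = 0),
               "regularization", class = "bwasrep_numeric_error")
  expect_silent(partial_correlation_matrix(ts, regularization = 0.1))
})

test_that("vectorize_edges returns the strict upper triangle row-major", {
  m <- matrix(c(1, 2, 3, 2, 1, 4, 3, 4, 1), 3, 3)
  v <- vectorize_edges(m)
  expect_identical(unname(v), c(2, 3, 4))  # (1,2), (1,3), (2,3)
  expect_identical(names(v), c("e1_2", "e1_3", "e2_3"))
  expect_identical(unname(vectorize_edges(diag(4))), rep(0, 6))
  expect_length(vectorize_edges(diag(100)), 4950)
  asym <- m; asym[1, 2] <- 5
  expect_error(vectorize_edges(asym), class = "bwasrep_validation_error")
})

test_that("ridge with tiny shrinkage recovers an exact linear signal", {
  set.seed(4)
  x <- matrix(rnorm(50 * 10), 50, 10)
  y <- x[, 1]
  fit <- fit_model(x, model_spec("ridge", ridge_shrinkage = 1e-8), y = y)
  expect_gte(prediction_outcome_r(predict(fit, x), y), 0.999)
})

test_that("near-interpolating ridge overfits any outcome when p >= n - 1", {
  set.seed(5)
  x <- matrix(rnorm(30 * 60), 30, 60)
  y <- rnorm(30)
  fit <- fit_model(x, model_spec("ridge", ridge_shrinkage = 1e-8), y = y)
  expect_gte(prediction_outcome_r(predict(fit, x), y), 0.99)
})

test_that("primal and dual ridge solutions coincide", {
  set.seed(6)
  x <- matrix(rnorm(40 * 40), 40, 40)
  y <- rnorm(40)
  spec <- model_spec("ridge", ridge_shrinkage = 2)
  fit <- fit_model(x[, 1:39], spec, y = y)       # primal branch (p < n)
  xs <- scale(x[, 1:39])
  beta_ref <- solve(crossprod(xs) + diag(2, 39), crossprod(xs, y - mean(y)))
  expect_equal(unname(fit$state$beta), drop(beta_ref), tolerance = 1e-10)
  fit2 <- fit_model(x, spec, y = y)              # dual branch (p = n)
  xs2 <- scale(x)
  beta_ref2 <- solve(crossprod(xs2) + diag(2, 40), crossprod(xs2, y - mean(y)))
  expect_equal(unname(fit2$state$beta), drop(beta_ref2), tolerance = 1e-8)
})

test_that("ridge solution agrees with an independent coordinate-descent fit", {
  set.seed(11)
  n <- 80
  x <- matrix(rnorm(n * 15), n, 15)
  y <- x[, 2] * 0.5 + rnorm(n)
  shrink <- 3
  fit <- fit_model(x, model_spec("ridge", ridge_shrinkage = shrink), y = y)
  xs <- scale(x)
  # glmnet standardizes y internally: its ridge lambda maps to
  # shrinkage * sd_n(y) / n for the (X^T X + shrinkage I) solution
  sd_n <- sqrt(mean((y - mean(y))^2))
  g <- glmnet::glmnet(xs, y, alpha = 0, lambda = shrink * sd_n / n,
                      standardize = FALSE, intercept = TRUE, thresh = 1e-14)
  beta_g <- as.numeric(g$beta)
  expect_equal(unname(fit$state$beta), beta_g, tolerance = 1e-6)
})

test_that("predictions are pure and shrinkage -> Inf approaches the outcome mean", {
  ds <- small_dataset(n = 60, p = 10)
  fit <- fit_model(ds, model_spec("ridge"))
  expect_identical(predict(fit, ds), predict(fit, ds))
  big <- fit_model(ds, model_spec("ridge", ridge_shrinkage = 1e12))
  expect_equal(predict(big, ds), rep(mean(ds$outcome), nrow(ds)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # single observation input
  x <- as.matrix(ds[, grep("^f", names(ds))])
  expect_length(predict(fit, x[1, ]), 1)
})

test_that("fit errors on constant outcomes and undersized samples", {
  set.seed(7)
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_model(x, y = rep(1, 10)), class = "bwasrep_fit_error")
  expect_error(fit_model(x[1:3, ], y = rnorm(3)), class = "bwasrep_size_error")
  fit <- fit_model(x, y = rnorm(10))
  expect_error(predict(fit, x[, 1:3]), class = "bwasrep_shape_error")
})

test_that("pca_svr retains at most n_train - 1 components and respects the cap", {
  set.seed(8)
  x <- matrix(rnorm(20 * 100), 20, 100)
  y <- rnorm(20)
  fit <- fit_model(x, model_spec("pca_svr"), y = y)
  expect_lte(fit$state$n_components, 19)
  capped <- fit_model(x, model_spec("pca_svr", pca_max_components = 5), y = y)
  expect_identical(capped$state$n_components, 5L)
})

test_that("pca_svr overfits permuted outcomes in-sample at high dimension", {
  ds <- simulate_bwas_data(100, 500, rho_true = 0.3, seed = 9)
  rs <- vapply(1:20, function(i) {
    perm <- permute_outcome(ds, seed = i)
    fit <- fit_model(perm, model_spec("pca_svr"))
    prediction_outcome_r(predict(fit, perm), perm$outcome)
  }, numeric(1))
  expect_gt(mean(rs), 0.3)
})

test_that("cross-validation is seeded, balanced and leakage-free", {
  ds <- small_dataset(n = 55, p = 8, rho = 0.6)
  cv1 <- cv_predictions(ds, model_spec("ridge"), k_folds = 5, seed = 3)
  cv2 <- cv_predictions(ds, model_spec("ridge"), k_folds = 5, seed = 3)
  expect_identical(cv1, cv2)
  expect_true(all(table(cv1$fold) %in% c(11L)))
  # corrupting a held-out fold's outcomes must not change its predictions
  parts <- bwasrep:::bwas_xy(ds)
  y_corrupt <- parts$y
  corrupt_idx <- which(cv1$fold == 2)
  y_corrupt[corrupt_idx] <- y_corrupt[corrupt_idx] + 100
  cv3 <- cv_predictions(parts$x, model_spec("ridge"), k_folds = 5, seed = 3,
                        y = y_corrupt)
  expect_identical(cv1$predicted[corrupt_idx], cv3$predicted[corrupt_idx])
})

test_that("leave-one-out recovers a strong linear signal out of fold", {
  set.seed(10)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- x[, 1]
  cv <- cv_predictions(x, model_spec("ridge", ridge_shrinkage = 1e-8),
                       k_folds = 40, seed = 1, y = y)
  expect_gte(prediction_outcome_r(cv$predicted, cv$observed), 0.99)
  expect_error(cv_predictions(x, k_folds = 41, y = y),
               class = "bwasrep_size_error")
})

test_that("ridge predictions are invariant to affine feature rescaling", {
  ds <- small_dataset(n = 80, p = 12, rho = 0.5)
  x <- as.matrix(ds[, grep("^f", names(ds))])
  y <- ds$outcome
  spec <- model_spec("ridge")
  p1 <- predict(fit_model(x, spec, y = y), x)
  x2 <- sweep(sweep(x, 2, seq_len(12) * 3, "*"), 2, seq_len(12), "+")
  p2 <- predict(fit_model(x2, spec, y = y), x2)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("tidy and glance expose weights and metadata", {
  ds <- small_dataset(n = 60, p = 10)
  fit <- fit_model(ds, model_spec("ridge"))
  td <- tidy(fit)
  expect_identical(nrow(td), 10L)
  expect_identical(td$term[1], "f0001")
  gl <- glance(fit)
  expect_identical(gl$family, "ridge")
  # tidy weights reproduce predictions on raw features up to the intercept
  x <- as.matrix(ds[, grep("^f", names(ds))])
  manual <- drop(x %*% td$estimate)
  expect_equal(cor(manual, predict(fit, ds)), 1, tolerance = 1e-10)
})
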