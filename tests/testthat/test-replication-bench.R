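test_that("draw_pair yields disjoint, seeded subsets and exhausts the sample at n/2", {
  ds <- small_dataset(n = 60, p = 5)
  pair <- draw_pair(ds, 20, seed = 1)
  expect_identical(nrow(pair$discovery), 20L)
  expect_identical(nrow(pair$replication), 20L)
  expect_length(intersect(pair$discovery$sample_id,
                          pair$replication$sample_id), 0)
  expect_identical(draw_pair(ds, 20, seed = 1), pair)
  # n = size/2 partitions the full sample
  full <- draw_pair(ds, 30, seed = 2)
  expect_setequal(c(full$discovery$sample_id, full$replication$sample_id),
                  ds$sample_id)
  expect_error(draw_pair(ds, 31, seed = 1), "60",
               class = "bwasrep_size_error")
})

test_that("repeated draws behave like without-replacement sampling", {
  ds <- small_dataset(n = 40, p = 4)
  # each sample appears in the discovery half with probability n/N
  hits <- rowSums(vapply(1:300, function(s) {
    ds$sample_id %in% draw_pair(ds, 10, seed = s)$discovery$sample_id
  }, logical(40)))
  p_hat <- hits / 300
  expect_lt(max(abs(p_hat - 0.25)), 4 * sqrt(0.25 * 0.75 / 300))
})

test_that("run_replicate records all three effect sizes correctly", {
  ds <- simulate_bwas_data(500, 30, rho_true = 0.9, n_signal = 8, seed = 9)
  rec <- run_replicate(ds, 200, model_spec("ridge"), seed = 3)
  expect_gt(rec$r_disc_cv, 0.8)
  expect_gt(rec$r_rep, 0.8)
  expect_gt(rec$r_disc_insample, rec$r_disc_cv - 0.05)
  expect_identical(run_replicate(ds, 200, model_spec("ridge"), seed = 3), rec)
  # permuted outcomes: in-sample inflated, replication near zero
  perm <- permute_outcome(simulate_bwas_data(300, 200, rho_true = 0.5, seed = 10),
                          seed = 1)
  rec0 <- run_replicate(perm, 100, model_spec("ridge"), seed = 4)
  expect_gt(rec0$r_disc_insample, 0.5)
  expect_lt(abs(rec0$r_rep), 0.3)
})

test_that("run_benchmark counts, derives seeds stably, and fails fast", {
  ds <- small_dataset(n = 220, p = 10, rho = 0.4)
  cfg10 <- benchmark_config(n_grid = c(50, 100), n_bootstrap = 10,
                            k_folds = 5, seed = 2)
  b10 <- run_benchmark(ds, cfg10)
  expect_identical(nrow(b10), 20L)
  expect_identical(sort(unique(b10$n)), c(50L, 100L))
  # extending B leaves earlier replicates unchanged
  cfg5 <- benchmark_config(n_grid = c(50, 100), n_bootstrap = 5,
                           k_folds = 5, seed = 2)
  b5 <- run_benchmark(ds, cfg5)
  merged <- dplyr::semi_join(tibble::as_tibble(b10), tibble::as_tibble(b5),
                             by = c("n", "replicate"))
  expect_equal(merged, tibble::as_tibble(b5), ignore_attr = TRUE)
  expect_error(
    run_benchmark(ds, benchmark_config(n_grid = c(50, 150), seed = 1)),
    class = "bwasrep_size_error"
  )
})

test_that("aggregate_benchmark computes the metrics of a constructed table", {
  rec <- constructed_records(n_total = 100, n_disc_pos = 80, n_both_pos = 60)
  tab <- aggregate_benchmark(rec, alpha = 0.05,
                             conditioning = "discovery_significant",
                             n_boot = 50)
  get <- function(m) tab$value[tab$metric == m]
  expect_identical(get("power"), 0.8)
  expect_identical(get("p_rep"), 0.75)
  expect_equal(get("mean_inflation_insample"),
               mean(rec$r_disc_insample - rec$r_rep), tolerance = 1e-12)
  expect_identical(tab$subset_n[tab$metric == "p_rep"], 80L)
  # all-significant records: conditional equals unconditional inflation
  all_pos <- constructed_records(100, 100, 100)
  tab2 <- aggregate_benchmark(all_pos, alpha = 0.05, n_boot = 50)
  expect_identical(tab2$value[tab2$metric == "power"], 1)
  expect_identical(tab2$value[tab2$metric == "p_rep"], 1)
  expect_equal(tab2$value[tab2$metric == "conditional_inflation"],
               tab2$value[tab2$metric == "mean_inflation_cv"],
               tolerance = 1e-12)
  # no discovery-positive records: sentinel, never a silent zero
  none <- constructed_records(50, 0, 0)
  tab3 <- aggregate_benchmark(none, alpha = 0.05, n_boot = 50)
  expect_identical(tab3$value[tab3$metric == "power"], 0)
  expect_true(is.na(tab3$value[tab3$metric == "p_rep"]))
  expect_identical(tab3$subset_n[tab3$metric == "p_rep"], 0L)
})

test_that("min_n finds the first crossing and the above-grid sentinel", {
  tab <- tibble::tibble(
    n = c(75, 150, 300, 500), metric = "power",
    value = c(0.4, 0.7, 0.85, 0.95)
  )
  expect_identical(as.integer(min_n(tab, "power", 0.8)), 300L)
  low <- tab
  low$value <- c(0.1, 0.2, 0.3, 0.4)
  sentinel <- min_n(low, "power", 0.8)
  expect_identical(unclass(sentinel)[1], Inf)
  expect_identical(attr(sentinel, "label"), ">500")
  wiggly <- tibble::tibble(n = c(75, 150, 300), metric = "power",
                           value = c(0.85, 0.7, 0.9))
  expect_warning(res <- min_n(wiggly, "power", 0.8), "monotone")
  expect_identical(as.integer(res), 75L)
  expect_error(min_n(tab, "accuracy"))
})

test_that("full_sample_effect matches the attenuation expected of near-OLS ridge", {
  ds <- simulate_bwas_data(1200, 200, rho_true = 0.3, seed = 11)
  est <- full_sample_effect(ds, model_spec("ridge"), seed = 3)
  # weak shrinkage at p/n_train ~ 0.19 attenuates the CV estimate below
  # rho_true: closed-form OLS attenuation rho / sqrt(1 + (p/n)(1-rho^2)/rho^2)
  rho <- 0.3
  oracle <- rho / sqrt(1 + (200 / 1080) * (1 - rho^2) / rho^2)
  expect_lt(abs(est$r - oracle), 0.09)
  expect_lt(est$r, rho + 0.03)  # CV never optimistic about the truth
  expect_identical(est$method, "cv")
  expect_identical(full_sample_effect(ds, model_spec("ridge"), seed = 3)$r,
                   est$r)
})

test_that("under the null the full-sample CV estimate is centred at or slightly below zero", {
  # the CV null is mildly pessimistic (negative mean) and somewhat wider
  # than the parametric correlation null; it must not be systematically
  # positive, which is the bias CV exists to remove
  rs <- vapply(1:20, function(s) {
    ds <- simulate_bwas_data(150, 20, rho_true = 0, seed = 100 + s)
    full_sample_effect(ds, model_spec("ridge"), k_folds = 5, seed = s)$r
  }, numeric(1))
  expect_lte(mean(rs), 0.02)
  expect_gte(mean(rs), -0.12)
  expect_lt(sd(rs), 3 / sqrt(150))
})

test_that("benchmark variance of the CV estimate shrinks with sample size", {
  ds <- simulate_bwas_data(900, 50, rho_true = 0.4, seed = 12)
  cfg <- benchmark_config(n_grid = c(50, 400), n_bootstrap = 30,
                          k_folds = 5, seed = 3)
  bench <- run_benchmark(ds, cfg)
  s <- tapply(bench$r_disc_cv, bench$n, sd)
  expect_gt(s[["50"]], s[["400"]])
  # pessimism at small n: mean CV estimate grows with n, never above truth + margin
  m <- tapply(bench$r_disc_cv, bench$n, mean)
  expect_lte(m[["50"]], m[["400"]])
  expect_lte(m[["400"]], 0.4 + 0.03)
})

test_that("glance summarises a benchmark run", {
  ds <- small_dataset(n = 120, p = 8, rho = 0.3)
  bench <- run_benchmark(ds, benchmark_config(n_grid = 40, n_bootstrap = 4,
                                              k_folds = 4, seed = 9))
  gl <- glance(bench)
  expect_identical(gl$n_records, 4L)
  expect_identical(gl$model, "ridge")
  expect_identical(gl$n_invalid, 0L)
})
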