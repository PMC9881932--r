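# The experiment-scale behavior (calibration at the preset size, the power
# grid) is exercised in test-acceptance.R; these tests cover the machinery at
# small problem sizes.

small_null <- sim_params(m = 120, n1 = 40, n0 = 40, k0 = 10, signal_strength = 0)

test_that("a constant component can never reject; strong signal almost always does", {
  sim <- simulate_paca_data(sim_params(
    m = 120, n1 = 40, n0 = 40, k0 = 5, signal_strength = 5, seed = 80
  ))
  const_fn <- function(x, y) rep(1, ncol(x))
  res <- structure_significance_test(const_fn, sim$x, sim$y, n_perm = 19, seed = 1)
  expect_false(res$reject)
  expect_gte(res$p_value, 0.5)

  rejects <- vapply(1:20, function(r) {
    sim <- simulate_paca_data(sim_params(
      m = 120, n1 = 40, n0 = 40, k0 = 5, signal_strength = 5, seed = 800 + r
    ))
    structure_significance_test("paca", sim$x, sim$y, n_perm = 19,
                                seed = 80 + r)$reject
  }, logical(1))
  expect_gte(mean(rejects), 0.95)
})

test_that("null p-values are close to uniform and the test is calibrated", {
  pvals <- vapply(1:100, function(r) {
    p <- small_null; p$seed <- 9000 + r
    sim <- simulate_paca_data(p)
    cfg <- paca_config(seed = r, n_permutations = 20)
    structure_significance_test(top_component_fn("paca", cfg),
                                sim$x, sim$y, n_perm = 19, seed = 90 + r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
  expect_lte(mean(pvals <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("run_calibration reports rates, reproduces exactly, and flags broken methods", {
  always_reject <- as_test_fn(function(x, y, n_perm, level, seed) TRUE)
  res <- run_calibration(
    methods = list(paca = "paca", broken = always_reject),
    params = small_null, n_replicates = 12, n_perm = 19, seed = 42,
    config = paca_config(n_permutations = 20)
  )
  expect_identical(res$type1_rate[res$method == "broken"], 1)
  expect_equal(res$mc_se, sqrt(res$type1_rate * (1 - res$type1_rate) / 12))
  res2 <- run_calibration(
    methods = list(paca = "paca", broken = always_reject),
    params = small_null, n_replicates = 12, n_perm = 19, seed = 42,
    config = paca_config(n_permutations = 20)
  )
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(
    run_calibration(params = sim_params(signal_strength = 1), n_replicates = 5),
    "null data"
  )
})

test_that("run_power returns per-cell means, handles one rep, and orders by strength", {
  grid <- tibble::tibble(
    m = 150, n1 = 50, n0 = 50, k0 = 10,
    signal_strength = c(0.5, 5), sparsity = 1, prop = 0.5
  )
  res <- run_power(grid, methods = c("paca", "pca"), n_reps = 5, seed = 3,
                   config = paca_config(n_permutations = 20))
  expect_s3_class(res, "power_result")
  expect_identical(nrow(res), 4L)
  expect_true(all(res$mean_abs_corr >= 0 & res$mean_abs_corr <= 1))
  paca_rows <- dplyr::filter(res, method == "paca")
  expect_gt(
    paca_rows$mean_abs_corr[paca_rows$signal_strength == 5],
    paca_rows$mean_abs_corr[paca_rows$signal_strength == 0.5]
  )

  res1 <- run_power(grid[2, ], methods = "pca", n_reps = 1, seed = 4)
  expect_true(is.na(res1$se))
})

test_that("the oracle best-alpha contrastive mode runs and scores within range", {
  grid <- tibble::tibble(
    m = 100, n1 = 30, n0 = 30, k0 = 5,
    signal_strength = 4, sparsity = 1, prop = 0.5
  )
  res <- run_power(grid, methods = c("cpca_best", "cpca_inf"), n_reps = 3, seed = 8)
  expect_true(all(res$mean_abs_corr >= 0 & res$mean_abs_corr <= 1))
  expect_identical(nrow(res), 2L)
})

test_that("power collapses for contrastive methods under severe orthogonality violation", {
  grid <- tibble::tibble(
    m = 400, n1 = 200, n0 = 200, k0 = 80,
    signal_strength = 2, sparsity = 0.1, prop = 0.5,
    violation_rho = c(0, 0.3, 0.95)
  )
  res <- run_power(grid, methods = c("paca", "pca", "cpca_inf"), n_reps = 10,
                   seed = 5, config = paca_config(n_permutations = 20))
  pick <- function(mth, rho) {
    res$mean_abs_corr[res$method == mth & res$violation_rho == rho]
  }
  # contrastive methods collapse under severe violation
  expect_lt(pick("paca", 0.95), 0.3 * pick("paca", 0))
  expect_lt(pick("cpca_inf", 0.95), 0.3 * pick("cpca_inf", 0))
  # under weak-to-moderate violation PACA still leads the dominant-variation baseline
  expect_gt(pick("paca", 0.3), pick("pca", 0.3))
  # PCA's apparent power at severe violation reflects the confounded shared
  # axis, not genuine case-specific recovery (the false-tagging failure mode)
  expect_gt(pick("pca", 0.95), 0.5)
})
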