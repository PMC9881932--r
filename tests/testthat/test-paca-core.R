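test_that("pc_variance_pair matches rank-1 construction and eigensolver oracle", {
  # rank-1 cases, zero controls
  set.seed(20)
  m <- 80; n <- 12
  w <- rnorm(m); w <- w / sqrt(sum(w^2))
  s <- rnorm(n)
  x <- 3 * w %*% t(s)
  y <- matrix(0, m, n)
  pv <- pc_variance_pair(x, y)
  expect_lt(abs(pv$var_x - 9 * var(s)), 1e-8)
  expect_lt(abs(pv$var_y), 1e-12)
  expect_gt(abs_cos(pv$loading, w), 1 - 1e-8)

  # symmetry: identical matrices give identical variances
  z <- matrix(rnorm(m * n), m, n)
  pv2 <- pc_variance_pair(z, z)
  expect_lt(abs(pv2$var_x - pv2$var_y), 1e-10)

  # var_x equals the top eigenvalue of the sample covariance (independent path)
  x3 <- matrix(rnorm(100 * 20), 100, 20)
  y3 <- matrix(rnorm(100 * 25), 100, 25)
  pv3 <- pc_variance_pair(x3, y3)
  ev <- eigen(stats::cov(t(x3)), symmetric = TRUE, only.values = TRUE)$values[1]
  expect_lt(abs(pv3$var_x - ev), 1e-8)

  # zero residual: flagged, not an error
  pv4 <- pc_variance_pair(matrix(0, 10, 4), matrix(0, 10, 4))
  expect_true(pv4$degenerate)
  expect_identical(pv4$var_x, 0)
})

test_that("permutation null is invariant for constant loadings and reproducible", {
  set.seed(21)
  M <- matrix(rnorm(50 * 8), 50, 8)
  const <- rep(1 / sqrt(50), 50)
  null <- permutation_null_variance(const, M, 20, seed = 1)
  obs <- var(drop(crossprod(const, M)))
  expect_lt(max(abs(null - obs)), 1e-12)

  w <- rnorm(50); w <- w / sqrt(sum(w^2))
  expect_identical(
    permutation_null_variance(w, M, 25, seed = 9),
    permutation_null_variance(w, M, 25, seed = 9)
  )
})

test_that("a loading aligned with strong rank-1 structure beats its null", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    m <- 60; n <- 15
    w <- rnorm(m); w <- w / sqrt(sum(w^2))
    M <- 5 * w %*% t(rnorm(n)) + matrix(rnorm(m * n, sd = 0.5), m, n)
    obs <- var(drop(crossprod(w, M)))
    null <- permutation_null_variance(w, M, 100, seed = s + 1000)
    hits <- hits + (obs > max(null))
  }
  expect_gte(hits, 48)
})

test_that("scenario classification follows the four-way rule and the gamma ratio", {
  null <- seq(0.5, 1.5, length.out = 100)
  hi <- 5; lo <- 1 # 1 is below the 95% quantile of the null
  expect_identical(classify_scenario(hi, lo, null, null)$scenario, "i")
  expect_identical(classify_scenario(lo, hi, null, null)$scenario, "iv")
  expect_identical(classify_scenario(lo, lo, null, null)$scenario, "iii")
  expect_identical(classify_scenario(hi, hi, null, null)$scenario, "ii")
  # both significant with ratio above gamma: treated like case-specific
  cl <- classify_scenario(40, 2, null, null, gamma = 10)
  expect_identical(cl$scenario, "ii-ratio-pass")
  expect_equal(cl$ratio, 20)
  # zero control variance gives an infinite ratio (and case-specific handling),
  # never a division error
  cl0 <- classify_scenario(hi, 0, null, rep(0, 100))
  expect_identical(cl0$scenario, "i")
  expect_identical(cl0$ratio, Inf)
})

test_that("fit_paca separates strong dense subtypes and records the search", {
  sim <- simulate_paca_data(sim_params(
    m = 300, n1 = 100, n0 = 100, k0 = 30, signal_strength = 5,
    sparsity = 1, seed = 30
  ))
  fit <- fit_paca(sim$x, sim$y, paca_config(seed = 1))
  expect_gt(score_cor(fit, sim$truth), 0.9)
  expect_s3_class(fit$k_selection$trace, "tbl_df")
  expect_lte(nrow(fit$k_selection$trace), ceiling(log2(100)) + 2)
  # residual orthogonal to the removed basis (trivially so if nothing removed)
  expect_lt(max(abs(crossprod(fit$shared_basis, fit$x_residual)), 0), 1e-8)
  # loadings orthonormal, explained variance non-increasing
  expect_lt(max(abs(crossprod(fit$loadings) - diag(ncol(fit$loadings)))), 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-10))
  # tidy/glance accessors
  expect_identical(glance(fit)$k_selected, fit$k_selection$k_selected)
  expect_named(tidy(fit), c("sample_id", "component", "score"))
})

test_that("no shared structure gives k = 0 and a centered-X residual", {
  sim <- simulate_paca_data(sim_params(
    m = 120, n1 = 30, n0 = 30, k0 = 0, signal_strength = 0, seed = 31
  ))
  x <- as_feature_matrix(sim$x)
  fit <- fit_paca(x, sim$y, paca_config(seed = 2))
  expect_identical(fit$k_selection$k_selected, 0L)
  expect_equal(fit$x_residual, standardize(x), ignore_attr = TRUE)
})

test_that("scores are invariant to control sample order (up to sign)", {
  sim <- simulate_paca_data(sim_params(
    m = 200, n1 = 40, n0 = 40, k0 = 5, signal_strength = 3, seed = 32
  ))
  y <- as_feature_matrix(sim$y)
  set.seed(33)
  y_perm <- y[, sample(ncol(y))]
  f1 <- fit_paca(sim$x, y, paca_config(seed = 3), n_components = 2)
  f2 <- fit_paca(sim$x, y_perm, paca_config(seed = 3), n_components = 2)
  expect_identical(f1$k_selection$k_selected, f2$k_selection$k_selected)
  d <- min(
    max(abs(f1$scores[, 1] - f2$scores[, 1])),
    max(abs(f1$scores[, 1] + f2$scores[, 1]))
  )
  expect_lt(d, 1e-6)
})

test_that("selected k tracks the shared dimension at weak signal and shrinks as signal strengthens", {
  ks <- sapply(1:8, function(r) {
    vapply(c(weak = 1.25, strong = 5), function(s) {
      sim <- simulate_paca_data(sim_params(
        m = 200, n1 = 100, n0 = 100, k0 = 40, signal_strength = s,
        sparsity = 0.25, seed = 4000 + 17 * r
      ))
      fit <- suppressWarnings(fit_paca(sim$x, sim$y, paca_config(seed = r)))
      fit$k_selection$k_selected
    }, numeric(1))
  })
  # weak signal: the search settles near (at least half of) the true k0
  expect_gte(mean(ks["weak", ]), 20)
  expect_lte(mean(ks["weak", ]), 100)
  # stronger signal needs fewer axes removed
  expect_lt(mean(ks["strong", ]), mean(ks["weak", ]))
})

test_that("too few features for the CCA is redirected to rPACA", {
  pair <- random_pair(m = 10, n1 = 20, n0 = 20, seed = 34)
  expect_error(fit_paca(pair$x, pair$y), "fit_rpaca")
})
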