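test_that("PCA recovers rank-1 structure and matches an eigensolver oracle", {
  set.seed(40)
  m <- 50; n <- 10
  w <- rnorm(m)
  s <- rnorm(n)
  x <- w %*% t(s)
  rownames(x) <- paste0("f", 1:m)
  fit <- fit_pca(x, d = 1)
  expect_gt(abs_cos(fit$loadings[, 1], w), 1 - 1e-8)
  # variance of the projection of the centered data equals ||w||^2 var(s)
  expect_lt(abs(fit$variances[1] - sum(w^2) * var(s)), 1e-8)

  x2 <- matrix(rnorm(50 * 10), 50, 10)
  fit2 <- fit_pca(x2, d = 5)
  ev <- eigen(stats::cov(t(x2)), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(fit2$variances - ev[1:5])), 1e-8)
  expect_error(fit_pca(x2, d = 11), "must lie in")
})

test_that("contrastive PCA at alpha = 0 reduces exactly to PCA", {
  pair <- random_pair(m = 40, n1 = 8, n0 = 8, seed = 41)
  cp <- fit_cpca(pair$x, pair$y, alpha = 0, d = 3)
  pc <- fit_pca(pair$x, d = 3)
  expect_lt(max(abs(abs(cp$components) - abs(pc$loadings))), 1e-8)
  expect_lt(max(abs(abs(cp$scores) - abs(pc$scores))), 1e-8)
})

test_that("contrastive PCA matches a dense oracle and the identical-input identity", {
  pair <- random_pair(m = 20, n1 = 6, n0 = 7, seed = 42)
  alpha <- 2.5
  cp <- fit_cpca(pair$x, pair$y, alpha = alpha, d = 3)
  xc <- pair$x - rowMeans(pair$x)
  yc <- pair$y - rowMeans(pair$y)
  ee <- eigen(tcrossprod(xc) - alpha * tcrossprod(yc), symmetric = TRUE)
  expect_lt(max(abs(cp$values - ee$values[1:3])), 1e-8)
  for (j in 1:3) {
    expect_gt(abs_cos(cp$components[, j], ee$vectors[, j]), 1 - 1e-8)
  }

  # X = Y: contrast operator is (1 - alpha) Xc Xc'
  x2 <- pair$x
  colnames(x2) <- paste0("dup_", colnames(x2))
  cp2 <- fit_cpca(pair$x, x2, alpha = 0.25, d = 1)
  lam1 <- eigen(tcrossprod(xc), symmetric = TRUE, only.values = TRUE)$values[1]
  expect_lt(abs(cp2$values[1] - (1 - 0.25) * lam1), 1e-8)
})

test_that("cPCA is numerically continuous in alpha away from crossings", {
  pair <- random_pair(m = 30, n1 = 6, n0 = 6, seed = 43)
  a <- fit_cpca(pair$x, pair$y, alpha = 1.0, d = 1)
  b <- fit_cpca(pair$x, pair$y, alpha = 1.001, d = 1)
  expect_gt(abs_cos(a$components[, 1], b$components[, 1]), 1 - 1e-3)
})

test_that("infinite-alpha components live exactly in the controls' null space", {
  pair <- random_pair(m = 60, n1 = 10, n0 = 12, seed = 44)
  fit <- fit_cpca_inf(pair$x, pair$y, d = 4)
  yc <- pair$y - rowMeans(pair$y)
  expect_lt(max(abs(crossprod(yc, fit$components))), 1e-8)
  expect_lt(max(abs(crossprod(fit$components) - diag(4))), 1e-8)

  # zero background reduces to PCA
  y0 <- matrix(0, 60, 12, dimnames = dimnames(pair$y))
  f0 <- fit_cpca_inf(pair$x, y0, d = 2)
  pc <- fit_pca(pair$x, d = 2)
  expect_lt(max(abs(abs(f0$components) - abs(pc$loadings))), 1e-8)

  # more controls than features: only the zero solution exists
  wide <- random_pair(m = 8, n1 = 4, n0 = 10, seed = 45)
  expect_error(fit_cpca_inf(wide$x, wide$y), "rank-nullity")
})

test_that("near-saturated background leaves a single admissible direction", {
  # controls spanning all but one direction of feature space: rank-nullity
  # forces the unique remaining direction
  m <- 10; n0 <- m - 1
  Q <- random_orthonormal(m, m, seed = 46)
  left <- Q[, m] # the one direction outside the controls' span
  set.seed(48)
  S <- matrix(rnorm(n0 * 30), n0, 30)
  S <- S - rowMeans(S) # row-centered scores keep the centered span full
  y <- Q[, 1:n0] %*% S
  x <- matrix(rnorm(m * 12), m, 12)
  rownames(x) <- rownames(y) <- paste0("f", 1:m)
  colnames(x) <- paste0("c", 1:12); colnames(y) <- paste0("g", 1:30)
  fit <- fit_cpca_inf(x, y, d = 1)
  expect_gt(abs_cos(fit$components[, 1], left), 1 - 1e-6)
})

test_that("suggested alphas are a sorted subset of the grid, ten by default", {
  sim <- simulate_paca_data(sim_params(
    m = 80, n1 = 15, n0 = 15, k0 = 3, signal_strength = 2, seed = 49
  ))
  x <- as_feature_matrix(sim$x); y <- as_feature_matrix(sim$y)
  grid <- c(0, 10^seq(-1, 3, length.out = 39))
  alphas <- suggest_alphas(x, y, n_alphas = 10, grid = grid, seed = 5)
  expect_lte(length(alphas), 10)
  expect_true(all(alphas %in% grid))
  expect_identical(alphas, sort(alphas))
})

test_that("alphas collapse when the contrast has no structure to distinguish", {
  # shared-structure-free data at tiny alphas: all subspaces identical
  pair <- random_pair(m = 60, n1 = 10, n0 = 10, seed = 50)
  tiny <- c(1e-8, 2e-8, 5e-8, 1e-7, 2e-7)
  alphas <- suggest_alphas(pair$x, pair$y, n_alphas = 5, grid = tiny, seed = 6)
  expect_lte(length(alphas), 2)
})
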