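#' Randomized PACA for the many-samples regime
#'
#' Sample-space CCA requires more features than samples. When `m <=
#' max(n0, n1)`, this variant runs the full PACA residualization on repeated
#' random subsets of the samples (each subset small enough for the CCA), and
#' accumulates the implied case-sample covariance: for each batch, the
#' residualized case submatrix contributes the cross-products of its sampled
#' case columns, and each pair of cases is averaged over the batches in which
#' both were drawn. The eigenvectors of the aggregated n1 x n1 covariance give
#' the case-specific sample scores. With a single batch containing all samples
#' (possible only when `m > max(n0, n1)`) the procedure reduces exactly to
#' [fit_paca()] up to component signs. The subset scheme is a reconstruction
#' from a one-line description of the randomized variant; its exact published
#' protocol is not restated in these sources.
#'
#' @param x Case matrix or data frame (features x samples).
#' @param y Control matrix, same features.
#' @param subset_size Cases and controls drawn per batch (must be `< m`);
#'   defaults to `min(n1, n0, floor(3 * m / 4))`.
#' @param n_batches Number of random batches (default 50). Every pair of cases
#'   must co-occur in at least one batch; otherwise an error suggests more
#'   batches.
#' @param config A [paca_config()]; the shared dimension is selected
#'   independently within each batch, and `config$seed` drives all subsampling.
#' @param n_components Number of components to return.
#'
#' @return An object of class `"rpaca_fit"` (also `"paca_fit"` for the tidy /
#'   plotting methods): `scores` (n1 x D), `loadings` (m x D; case-matrix
#'   projections of the score directions, orthonormalized), `explained_variance`
#'   (eigenvalues of the aggregated covariance), `batch_k` (selected shared
#'   dimension per batch), and `covariance` (the aggregated n1 x n1 estimate).
#' @export
fit_rpaca <- function(x, y, subset_size = NULL, n_batches = 50,
                      config = paca_config(), n_components = NULL) {
  al <- check_pair(x, y)
  X <- standardize(al$x, config$standardization)
  Y <- standardize(al$y, config$standardization)
  m <- nrow(X); n1 <- ncol(X); n0 <- ncol(Y)
  subset_size <- as.integer(subset_size %||% min(n1, n0, floor(3 * m / 4)))
  if (subset_size >= m) {
    abort(sprintf("`subset_size` (%d) must be smaller than the number of features (%d).",
                  subset_size, m))
  }
  if (subset_size < 4) abort("`subset_size` must be at least 4.")
  full_batch <- subset_size == n1 && subset_size == n0

  cov_sum <- matrix(0, n1, n1)
  cov_cnt <- matrix(0, n1, n1)
  batch_k <- integer(n_batches)
  set.seed(config$seed)
  batch_seeds <- sample.int(2147483647L, n_batches)

  for (b in seq_len(n_batches)) {
    set.seed(batch_seeds[b])
    ci <- if (full_batch) seq_len(n1) else sort(sample.int(n1, subset_size))
    gi <- if (full_batch) seq_len(n0) else sort(sample.int(n0, subset_size))
    Xb <- X[, ci, drop = FALSE]
    Yb <- Y[, gi, drop = FALSE]
    bcfg <- config
    bcfg$seed <- batch_seeds[b]
    cs <- sample_space_cca(Xb, Yb, ridge_epsilon = config$ridge_epsilon)
    ks <- suppressWarnings(select_k(Xb, Yb, cs, bcfg))
    batch_k[b] <- ks$k_selected
    U <- shared_basis(cs, ks$k_selected, side = "x", type = config$shared_basis_type)
    xr <- residualize(Xb, U)
    xrc <- xr - rowMeans(xr)
    Cb <- crossprod(xrc)
    cov_sum[ci, ci] <- cov_sum[ci, ci] + Cb
    cov_cnt[ci, ci] <- cov_cnt[ci, ci] + 1
  }

  if (any(cov_cnt == 0)) {
    abort(sprintf(
      "%.0f case pair(s) were never co-sampled in %d batches; increase `n_batches` or `subset_size`.",
      sum(cov_cnt == 0) / 2, as.integer(n_batches)
    ))
  }
  K <- cov_sum / cov_cnt
  K <- (K + t(K)) / 2
  ee <- eigen(K, symmetric = TRUE)
  D <- min(n_components %||% config$max_components, n1 - 1L)
  vals <- pmax(ee$values[seq_len(D)], 0)
  V <- ee$vectors[, seq_len(D), drop = FALSE]
  scores <- sweep(V, 2, sqrt(vals), "*")
  for (j in seq_len(D)) {
    if (sign_of_largest(scores[, j]) < 0) scores[, j] <- -scores[, j]
  }
  # feature-space view of each component: project the centered cases onto the
  # score directions and orthonormalize
  xc <- X - rowMeans(X)
  L <- xc %*% V
  Lq <- qr.Q(qr(L))[, seq_len(D), drop = FALSE]
  for (j in seq_len(D)) {
    if (sign_of_largest(Lq[, j]) < 0) Lq[, j] <- -Lq[, j]
  }
  comp <- paste0("PAC", seq_len(D))
  dimnames(scores) <- list(colnames(X), comp)
  dimnames(Lq) <- list(rownames(X), comp)

  structure(
    list(
      scores = scores,
      loadings = Lq,
      explained_variance = vals / (m - 1),
      batch_k = batch_k,
      covariance = K,
      subset_size = subset_size,
      n_batches = as.integer(n_batches),
      config = config,
      dims = c(m = m, n1 = n1, n0 = n0)
    ),
    class = c("rpaca_fit")
  )
}

#' @export
print.rpaca_fit <- function(x, ...) {
  cat(sprintf(
    "<rpaca_fit> %d component(s) from %d batches of %d cases/controls\n",
    ncol(x$scores), x$n_batches, x$subset_size
  ))
  cat(sprintf("  per-batch shared dimension: median %g (range %d-%d)\n",
              stats::median(x$batch_k), min(x$batch_k), max(x$batch_k)))
  invisible(x)
}

#' @describeIn fit_rpaca Long-form scores.
#' @param x An `"rpaca_fit"`.
#' @param ... Unused.
#' @export
tidy.rpaca_fit <- function(x, ...) {
  mat_to_long(x$scores, "sample_id", "component", "score")
}

#' @describeIn fit_rpaca One-row summary.
#' @export
glance.rpaca_fit <- function(x, ...) {
  tibble::tibble(
    n_features = unname(x$dims["m"]),
    n_cases = unname(x$dims["n1"]),
    n_controls = unname(x$dims["n0"]),
    n_components = ncol(x$scores),
    n_batches = x$n_batches,
    subset_size = x$subset_size,
    median_batch_k = stats::median(x$batch_k)
  )
}
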