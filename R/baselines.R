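#' Principal components of the case matrix
#'
#' Baseline: top-d principal axes of the feature-centered case matrix, with
#' sample scores and explained variances.
#'
#' @param x Case matrix or data frame (features x samples).
#' @param d Number of components (`d <= min(m, n1)`).
#' @return An object of class `"pca_fit"` with `loadings` (m x d, orthonormal),
#'   `scores` (n1 x d), and `variances` (non-increasing).
#' @export
fit_pca <- function(x, d = 2) {
  X <- as_feature_matrix(x, arg = "x")
  m <- nrow(X); n <- ncol(X)
  if (d < 1 || d > min(m, n)) {
    abort(sprintf("`d` must lie in 1..min(m, n) = %d.", min(m, n)))
  }
  xc <- X - rowMeans(X)
  sv <- svd(xc, nu = d, nv = 0)
  loadings <- sv$u
  for (j in seq_len(d)) {
    if (sign_of_largest(loadings[, j]) < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- crossprod(xc, loadings)
  comp <- paste0("PC", seq_len(d))
  dimnames(loadings) <- list(rownames(X), comp)
  dimnames(scores) <- list(colnames(X), comp)
  structure(
    list(
      loadings = loadings, scores = scores,
      variances = sv$d[seq_len(d)]^2 / (n - 1),
      method = "pca"
    ),
    class = "pca_fit"
  )
}

#' Contrastive PCA with a finite contrast weight
#'
#' Finds the top-d eigenvectors of the contrast operator
#' `Xc Xc' - alpha * Yc Yc'` (each matrix centered by its own feature means):
#' directions that carry much case variance and little control variance.
#' `alpha = 0` reduces exactly to [fit_pca()] on the cases.
#'
#' @param x,y Feature-aligned case and control matrices (or data frames).
#' @param alpha Nonnegative finite contrast weight.
#' @param d Number of components.
#' @return An object of class `"cpca_fit"` with `alpha`, `components`
#'   (m x d, orthonormal), `scores` (n1 x d), and `values` (eigenvalues of the
#'   contrast operator, non-increasing).
#' @export
fit_cpca <- function(x, y, alpha = 1, d = 2) {
  if (!is.finite(alpha) || alpha < 0) {
    abort("`alpha` must be finite and nonnegative; use fit_cpca_inf() for the infinite limit.")
  }
  al <- check_pair(x, y)
  xc <- al$x - rowMeans(al$x)
  yc <- al$y - rowMeans(al$y)
  C <- tcrossprod(xc) - alpha * tcrossprod(yc)
  ee <- eigen(C, symmetric = TRUE)
  idx <- seq_len(d)
  V <- ee$vectors[, idx, drop = FALSE]
  for (j in idx) {
    if (sign_of_largest(V[, j]) < 0) V[, j] <- -V[, j]
  }
  scores <- crossprod(xc, V)
  comp <- paste0("cPC", idx)
  dimnames(V) <- list(rownames(xc), comp)
  dimnames(scores) <- list(colnames(xc), comp)
  structure(
    list(
      alpha = alpha, components = V, scores = scores,
      values = ee$values[idx], method = "cpca"
    ),
    class = "cpca_fit"
  )
}

#' Contrastive PCA in the infinite-contrast limit
#'
#' In the limit of an infinite contrast weight, every admissible component must
#' explain zero variance in the controls, i.e. lie in the null space of the
#' centered control matrix. This restricts components to an (m - rank(Yc))-
#' dimensional subspace, so more controls than features leaves only the zero
#' solution. The fit projects the centered cases onto that null space and takes
#' principal components there.
#'
#' @param x,y Feature-aligned case and control matrices (or data frames).
#' @param d Number of components.
#' @return A `"cpca_fit"` with `alpha = Inf`; every component `v` satisfies
#'   `Yc' v = 0`.
#' @export
fit_cpca_inf <- function(x, y, d = 2) {
  al <- check_pair(x, y)
  xc <- al$x - rowMeans(al$x)
  yc <- al$y - rowMeans(al$y)
  m <- nrow(xc); n0 <- ncol(yc)
  qy <- qr(yc)
  r0 <- qy$rank
  if (r0 >= m) {
    abort(sprintf(
      "The centered controls (n0 = %d) span all of the m = %d dimensional feature space; by rank-nullity only the zero solution exists.",
      n0, m
    ))
  }
  if (r0 > 0) {
    Qy <- qr.Q(qy)[, seq_len(r0), drop = FALSE]
    xp <- xc - Qy %*% crossprod(Qy, xc)
  } else {
    xp <- xc
  }
  sv <- svd(xp, nu = d, nv = 0)
  V <- sv$u
  for (j in seq_len(d)) {
    if (sign_of_largest(V[, j]) < 0) V[, j] <- -V[, j]
  }
  scores <- crossprod(xp, V)
  comp <- paste0("cPC", seq_len(d))
  dimnames(V) <- list(rownames(xc), comp)
  dimnames(scores) <- list(colnames(xc), comp)
  structure(
    list(
      alpha = Inf, components = V, scores = scores,
      values = sv$d[seq_len(d)]^2, method = "cpca_inf"
    ),
    class = "cpca_fit"
  )
}

#' Suggest representative contrast weights
#'
#' Reimplementation of the published heuristic for picking a handful of
#' informative contrast weights: fit contrastive PCA across a log-spaced grid
#' of alphas, measure the affinity between each pair of top-d subspaces as the
#' product of the cosines of their principal angles, spectrally cluster the
#' affinity matrix, and return the medoid alpha of each cluster. Clusters whose
#' representative subspaces are indistinguishable are merged, so on data with
#' no contrast structure the suggestions collapse to a few values. The exact
#' internals of the original selection algorithm are not restated in this
#' package's sources; treat the returned values as candidate settings, not as a
#' canonical list.
#'
#' @param x,y Feature-aligned case and control matrices (or data frames).
#' @param n_alphas Number of representatives to aim for (default 10).
#' @param grid Candidate alphas; defaults to 0 plus 39 log-spaced values in
#'   `[0.1, 1000]`.
#' @param d Subspace dimension used for the affinities.
#' @param seed Seed for the clustering step.
#' @return A sorted numeric vector of representative alphas (a subset of
#'   `grid`, at most `n_alphas` long).
#' @export
suggest_alphas <- function(x, y, n_alphas = 10, grid = NULL, d = 2, seed = 1L) {
  grid <- grid %||% c(0, 10^seq(-1, 3, length.out = 39))
  if (length(grid) == 0) abort("`grid` must be nonempty.")
  al <- check_pair(x, y)
  subspaces <- lapply(grid, function(a) fit_cpca(al$x, al$y, alpha = a, d = d)$components)
  G <- length(grid)
  A <- diag(1, G)
  for (i in seq_len(G - 1)) {
    for (j in seq((i + 1), G)) {
      s <- svd(crossprod(subspaces[[i]], subspaces[[j]]), nu = 0, nv = 0)$d
      A[i, j] <- A[j, i] <- min(prod(pmin(s, 1)), 1)
    }
  }
  k <- min(n_alphas, G)
  labs <- spectral_cluster(A, k, seed = seed)
  reps <- vapply(sort(unique(labs)), function(cl) {
    members <- which(labs == cl)
    # medoid: member with the highest total affinity to its cluster
    members[which.max(rowSums(A[members, members, drop = FALSE]))]
  }, integer(1))
  # merge representatives whose subspaces are essentially identical
  kept <- integer(0)
  for (r in reps[order(grid[reps])]) {
    if (!any(A[r, kept] > 1 - 1e-6)) kept <- c(kept, r)
  }
  sort(grid[kept])
}

# Normalized spectral clustering with kmeans on the leading eigenvectors.
spectral_cluster <- function(A, k, seed = 1L) {
  dg <- pmax(rowSums(A), .Machine$double.eps)
  L <- A / sqrt(dg %o% dg)
  ee <- eigen(L, symmetric = TRUE)
  E <- ee$vectors[, seq_len(k), drop = FALSE]
  nr <- sqrt(rowSums(E^2))
  E <- E / pmax(nr, .Machine$double.eps)
  distinct <- nrow(unique(round(E, 10)))
  k_eff <- min(k, distinct)
  if (k_eff >= nrow(E)) return(seq_len(nrow(E)))
  set.seed(seed)
  kmeans(E, centers = k_eff, nstart = 10, iter.max = 50)$cluster
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d component(s); top variance %.4g\n",
              ncol(x$scores), x$variances[1]))
  invisible(x)
}

#' @export
print.cpca_fit <- function(x, ...) {
  cat(sprintf("<cpca_fit> alpha = %s, %d component(s)\n",
              format(x$alpha), ncol(x$scores)))
  invisible(x)
}

#' @describeIn fit_pca Long-form scores.
#' @param x A fit object.
#' @param ... Unused.
#' @export
tidy.pca_fit <- function(x, ...) {
  mat_to_long(x$scores, "sample_id", "component", "score")
}

#' @describeIn fit_cpca Long-form scores.
#' @param x A fit object.
#' @param ... Unused.
#' @export
tidy.cpca_fit <- function(x, ...) {
  mat_to_long(x$scores, "sample_id", "component", "score")
}
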