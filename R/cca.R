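#' Canonical correlation analysis in the sample space
#'
#' Estimates the directions of variation shared between a case matrix `X`
#' (m features x n1 samples) and a control matrix `Y` (m x n0) by seeking
#' linear combinations of *samples* — vectors `a` in R^n1 and `b` in R^n0 —
#' whose feature-space images `X a` and `Y b` are maximally correlated, subject
#' to `||X a|| = ||Y b|| = 1`. With the sample Gram matrices
#' `S_XX = X'X`, `S_YY = Y'Y`, `S_XY = X'Y`, the case-side coefficients solve
#' the eigenproblem of `S_XX^{-1} S_XY S_YY^{-1} S_YX`; successive pairs are
#' orthogonal in the feature space. The computation uses the symmetric whitened
#' form `(S_XX+eI)^{-1/2} S_XY (S_YY+eI)^{-1} S_YX (S_XX+eI)^{-1/2}` via one
#' singular value decomposition, which yields all pairs at once with real,
#' sorted correlations.
#'
#' @param x Case matrix (features x samples), or a data frame accepted by
#'   [as_feature_matrix()]. Must be feature-aligned with `y`.
#' @param y Control matrix, same features in the same order.
#' @param r_max Number of canonical pairs to return; defaults to
#'   `min(n0, n1)` (all of them).
#' @param ridge_epsilon Ridge added to both Gram matrices; `NULL` uses
#'   `1e-8 * trace(S)/n` per side. An explicit `0` errors if a Gram matrix is
#'   numerically singular.
#'
#' @return An object of class `"canonical_system"` with elements
#'   `a_vectors` (n1 x R), `b_vectors` (n0 x R), `correlations` (length R,
#'   non-increasing, in `[0, 1]`), `u_directions` (m x R, unit-norm images
#'   `X a_r`), `v_directions` (m x R, unit-norm images `Y b_r`), and `R`.
#' @export
#' @examples
#' sim <- simulate_paca_data(sim_params(m = 60, n1 = 10, n0 = 10, k0 = 2, seed = 1))
#' cs <- sample_space_cca(sim$x, sim$y)
#' tidy(cs)
sample_space_cca <- function(x, y, r_max = NULL, ridge_epsilon = NULL) {
  X <- as_feature_matrix(x, arg = "x")
  Y <- as_feature_matrix(y, arg = "y")
  if (nrow(X) != nrow(Y) || !identical(rownames(X), rownames(Y))) {
    abort("`x` and `y` must be feature-aligned; see align_features().")
  }
  m <- nrow(X); n1 <- ncol(X); n0 <- ncol(Y)
  if (m <= max(n0, n1)) {
    abort(sprintf(
      "Sample-space CCA requires more features than samples (m = %d, max(n0, n1) = %d); use fit_rpaca() in this regime.",
      m, max(n0, n1)
    ))
  }
  R_all <- min(n0, n1)
  r_max <- r_max %||% R_all
  if (r_max > R_all) {
    abort(sprintf("`r_max` (%d) exceeds min(n0, n1) = %d.", r_max, R_all))
  }

  Sxx <- crossprod(X)
  Syy <- crossprod(Y)
  Sxy <- crossprod(X, Y)

  Wx <- inv_sqrt_gram(Sxx, ridge_epsilon, side = "x")
  Wy <- inv_sqrt_gram(Syy, ridge_epsilon, side = "y")

  TT <- Wx %*% Sxy %*% Wy
  sv <- svd(TT, nu = r_max, nv = r_max)
  rho <- pmin(pmax(sv$d[seq_len(r_max)], 0), 1)

  A <- Wx %*% sv$u
  B <- Wy %*% sv$v
  U <- X %*% A
  V <- Y %*% B
  # enforce the unit-norm constraint exactly (the ridge perturbs it slightly)
  nu <- sqrt(colSums(U^2)); nv <- sqrt(colSums(V^2))
  A <- sweep(A, 2, nu, "/"); U <- sweep(U, 2, nu, "/")
  B <- sweep(B, 2, nv, "/"); V <- sweep(V, 2, nv, "/")

  for (r in seq_len(r_max)) {
    su <- sign_of_largest(U[, r])
    if (su < 0) { U[, r] <- -U[, r]; A[, r] <- -A[, r] }
    if (sum(U[, r] * V[, r]) < 0) { V[, r] <- -V[, r]; B[, r] <- -B[, r] }
  }
  dimnames(U) <- list(rownames(X), paste0("cc", seq_len(r_max)))
  dimnames(V) <- dimnames(U)
  dimnames(A) <- list(colnames(X), colnames(U))
  dimnames(B) <- list(colnames(Y), colnames(U))

  structure(
    list(
      a_vectors = A, b_vectors = B,
      correlations = rho,
      u_directions = U, v_directions = V,
      R = r_max, n1 = n1, n0 = n0, m = m
    ),
    class = "canonical_system"
  )
}

# Inverse square root of a sample Gram matrix, with a relative ridge.
inv_sqrt_gram <- function(S, ridge_epsilon, side = "x") {
  n <- nrow(S)
  eps <- ridge_epsilon %||% (1e-8 * sum(diag(S)) / n)
  ee <- eigen(S, symmetric = TRUE)
  vals <- ee$values + eps
  if (min(vals) <= max(vals) * .Machine$double.eps * n) {
    abort(sprintf(
      "Gram matrix of `%s` is numerically singular; supply a positive `ridge_epsilon`.",
      side
    ))
  }
  ee$vectors %*% (t(ee$vectors) / sqrt(vals))
}

sign_of_largest <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) 1 else s
}

#' Orthonormal basis for the top shared directions
#'
#' Takes the first `k` case-side shared directions of a [sample_space_cca()]
#' fit and re-orthonormalizes them in order (QR), preserving the span of every
#' leading subset. With a zero ridge the raw directions are already orthogonal;
#' the finite ridge perturbs that slightly, and the residualization step
#' requires an exactly orthonormal basis. Column signs are fixed so each
#' column's largest-magnitude entry is positive.
#'
#' @param cs A `"canonical_system"`.
#' @param k Number of directions (`0 <= k <= cs$R`). `k = 0` returns an
#'   m x 0 matrix.
#' @param side `"x"` (default) for the case-side directions, `"y"` for the
#'   controls' own image of the shared axes.
#' @param type `"orthonormal"` (default) or `"raw"`.
#' @return An m x k matrix with orthonormal columns.
#' @export
shared_basis <- function(cs, k, side = c("x", "y"), type = c("orthonormal", "raw")) {
  side <- match.arg(side)
  type <- match.arg(type)
  stopifnot(inherits(cs, "canonical_system"))
  if (k > cs$R) abort(sprintf("`k` (%d) exceeds the number of canonical pairs (%d).", k, cs$R))
  D <- if (side == "x") cs$u_directions else cs$v_directions
  if (k == 0) return(D[, 0, drop = FALSE])
  U <- D[, seq_len(k), drop = FALSE]
  if (type == "raw") return(U)
  Q <- qr.Q(qr(U))[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (sign_of_largest(Q[, j]) < 0) Q[, j] <- -Q[, j]
  }
  rownames(Q) <- rownames(D)
  colnames(Q) <- colnames(U)
  Q
}

#' Remove the expected effect of known directions from a matrix
#'
#' Orthogonal projection of each sample (column) onto the complement of
#' `span(U)`: returns `M - U (U' M)`. With `U` the estimated shared basis this
#' removes the expected contribution of the shared sources of variation from
#' the case matrix.
#'
#' @param m Feature-by-sample matrix (or data frame).
#' @param u Matrix with orthonormal columns and the same number of rows.
#' @return A matrix of the same shape with `U' result = 0`.
#' @export
residualize <- function(m, u) {
  M <- as_feature_matrix(m, arg = "m")
  if (!is.matrix(u)) abort("`u` must be a matrix.")
  if (ncol(u) == 0) return(M)
  if (nrow(u) != nrow(M)) {
    abort(sprintf("`u` has %d rows but `m` has %d features.", nrow(u), nrow(M)))
  }
  M - u %*% crossprod(u, M)
}

#' @export
print.canonical_system <- function(x, ...) {
  cat(sprintf(
    "<canonical_system> %d canonical pairs (m = %d, n1 = %d, n0 = %d)\n",
    x$R, x$m, x$n1, x$n0
  ))
  cat("  top correlations:", paste(format(head(x$correlations, 5), digits = 3),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn sample_space_cca One row per canonical pair with its
#'   correlation.
#' @param x A `"canonical_system"` object.
#' @param ... Unused.
#' @export
tidy.canonical_system <- function(x, ...) {
  tibble::tibble(component = seq_len(x$R), correlation = x$correlations)
}

#' Scree plot of canonical correlations
#'
#' @param object A `"canonical_system"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.canonical_system <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$component, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Canonical pair", y = "Canonical correlation") +
    ggplot2::theme_minimal()
}
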