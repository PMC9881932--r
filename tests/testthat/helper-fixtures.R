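# Small deterministic fixtures shared across test files.

random_pair <- function(m = 30, n1 = 5, n0 = 5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(m * n1), m, n1,
              dimnames = list(paste0("f", seq_len(m)), paste0("c", seq_len(n1))))
  y <- matrix(rnorm(m * n0), m, n0,
              dimnames = list(paste0("f", seq_len(m)), paste0("g", seq_len(n0))))
  list(x = x, y = y)
}

random_orthonormal <- function(m, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(m * k), m, k)))
}

# Brute-force sample-space CCA for tiny instances, built directly from the
# defining eigenproblem on S_XX^{-1} S_XY S_YY^{-1} S_YX (no whitening, no
# ridge). Serves as the independent oracle.
naive_cca <- function(x, y) {
  sxx <- crossprod(x); syy <- crossprod(y); sxy <- crossprod(x, y)
  op <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ee <- eigen(op)
  vals <- Re(ee$values)
  a <- Re(ee$vectors)
  a <- sweep(a, 2, sqrt(colSums((x %*% a)^2)), "/")
  b <- solve(syy) %*% t(sxy) %*% a
  b <- sweep(b, 2, sqrt(colSums((y %*% b)^2)), "/")
  list(rho = sqrt(pmax(vals, 0)), a = a, b = b)
}

abs_cos <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

# Largest principal angle (degrees) between the column spaces of two bases.
max_principal_angle <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  s <- pmin(svd(crossprod(qa, qb))$d, 1)
  max(acos(s)) * 180 / pi
}

score_cor <- function(fit, truth) abs(cor(fit$scores[, 1], truth$subtype_labels))
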