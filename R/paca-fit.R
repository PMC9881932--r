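#' Top-PC variance in cases and the variance it explains in controls
#'
#' Computes the first principal axis of the residualized case matrix (a unit
#' vector over features) and evaluates (a) the variance of its projection
#' across case samples and (b) the variance the *same* loading explains across
#' control samples. The contrast between the two is what the shared-dimension
#' search classifies at each candidate k.
#'
#' @param x_res Residualized case matrix (features x samples).
#' @param y_res Residualized control matrix, feature-aligned with `x_res`.
#' @return A list with `loading` (unit m-vector), `var_x`, `var_y`, and
#'   `degenerate` (`TRUE` when `x_res` is numerically zero, in which case
#'   `var_x = 0` is returned rather than an error).
#' @export
pc_variance_pair <- function(x_res, y_res) {
  if (nrow(x_res) != nrow(y_res)) abort("`x_res` and `y_res` must be feature-aligned.")
  xc <- x_res - rowMeans(x_res)
  if (max(abs(xc)) < 1e-12) {
    return(list(loading = numeric(nrow(x_res)), var_x = 0, var_y = 0,
                degenerate = TRUE))
  }
  sv <- svd(xc, nu = 1, nv = 0)
  w <- drop(sv$u)
  if (sign_of_largest(w) < 0) w <- -w
  list(
    loading = w,
    var_x = var(drop(crossprod(w, x_res))),
    var_y = var(drop(crossprod(w, y_res))),
    degenerate = FALSE
  )
}

#' Permutation null for a projection variance
#'
#' The observed statistic at each step of the shared-dimension search is the
#' variance of `loading' M` across samples. Its null distribution is obtained
#' by permuting the entries of the loading vector uniformly at random: a
#' permuted loading no longer aligns with any coherent structure in `M`, so the
#' null reflects the variance a generic unit vector explains.
#'
#' @param loading Unit vector over features.
#' @param m Feature-by-sample matrix.
#' @param n_permutations Number of permutations (>= 10).
#' @param seed Integer seed; fixed seed gives identical null vectors.
#' @return Numeric vector of `n_permutations` null variances.
#' @export
permutation_null_variance <- function(loading, m, n_permutations = 100, seed = 1L) {
  if (n_permutations < 10) abort("`n_permutations` must be >= 10.")
  M <- if (is.matrix(m)) m else as_feature_matrix(m, arg = "m")
  p <- nrow(M)
  if (length(loading) != p) abort("`loading` length must match the number of features.")
  set.seed(seed)
  P <- vapply(seq_len(n_permutations), function(i) loading[sample.int(p)],
              numeric(p))
  proj <- crossprod(P, M) # n_permutations x n
  n <- ncol(M)
  mu <- rowMeans(proj)
  rowSums((proj - mu)^2) / (n - 1)
}

#' Classify a candidate component against its permutation nulls
#'
#' A projection variance is called significant when it exceeds the
#' `(1 - level)` empirical quantile of its permutation null. Four scenarios
#' follow: `"i"` — significant variation in cases but not controls (a
#' case-specific component); `"ii"` — significant in both (residual shared
#' variation); `"iii"` — in neither (all structure removed); `"iv"` —
#' significant in controls only (a model-assumption violation). Under `"ii"`,
#' if the case/control variance ratio exceeds `gamma` the component is treated
#' like case (i) and reported as `"ii-ratio-pass"`; a zero control variance
#' gives an infinite ratio and therefore also passes.
#'
#' @param var_x,var_y Observed projection variances in cases and controls.
#' @param null_x,null_y Permutation null distributions (numeric vectors).
#' @param level One-sided significance level in `(0, 1)`.
#' @param gamma Positive variance-ratio threshold.
#' @return A list with `scenario` (one of `"i"`, `"ii"`, `"iii"`, `"iv"`,
#'   `"ii-ratio-pass"`), `ratio`, and the null quantiles used.
#' @export
classify_scenario <- function(var_x, var_y, null_x, null_y,
                              level = 0.05, gamma = 10) {
  if (level <= 0 || level >= 1) abort("`level` must lie in (0, 1).")
  if (gamma <= 0) abort("`gamma` must be positive.")
  qx <- quantile(null_x, 1 - level, names = FALSE)
  qy <- quantile(null_y, 1 - level, names = FALSE)
  sig_x <- var_x > qx
  sig_y <- var_y > qy
  ratio <- if (var_y < .Machine$double.eps) Inf else var_x / var_y
  scenario <- if (sig_x && !sig_y) {
    "i"
  } else if (sig_x && sig_y) {
    if (ratio > gamma) "ii-ratio-pass" else "ii"
  } else if (!sig_x && !sig_y) {
    "iii"
  } else {
    "iv"
  }
  list(scenario = scenario, ratio = ratio, null_quantile_x = qx, null_quantile_y = qy)
}

#' Binary search for the effective shared dimension
#'
#' Searches k in `0..min(n0, n1)` for the minimal number of shared axes whose
#' removal exposes structure unique to the cases; k = 0 (remove nothing) is
#' probed first and the binary search over `1..min(n0, n1)` opens only when
#' residual shared variation is present. At each candidate k, both
#' matrices are residualized against their top-k shared directions (the
#' controls against their own image of the shared axes by default), the top PC
#' of the residualized cases is extracted, and its variance in cases and
#' controls is classified against permutation nulls (see
#' [classify_scenario()]). Scenarios i, iii and ii-ratio-pass direct the search
#' to smaller k (possible over-correction), scenario ii to larger k (residual
#' shared variation), and scenario iv terminates the search as a violation of
#' the model assumption. The selected k is the smallest visited candidate whose
#' scenario was i or ii-ratio-pass, or 0 when no candidate exposed
#' case-specific structure.
#'
#' @param x,y Standardized, feature-aligned case and control matrices (the same
#'   matrices the canonical system was computed from).
#' @param cs A [sample_space_cca()] fit of `(x, y)`.
#' @param config A [paca_config()].
#' @return An object of class `"k_selection"`: `k_selected`, `terminated_by`
#'   (`"converged"`, `"scenario_iv"`, or `"exhausted"`), and `trace`, a tibble
#'   with one row per probe (`k_candidate`, `scenario`, `var_x`, `var_y`,
#'   `null_quantile_x`, `null_quantile_y`, `ratio`).
#' @export
select_k <- function(x, y, cs, config = paca_config()) {
  stopifnot(inherits(cs, "canonical_system"))
  X <- if (is.matrix(x)) x else as_feature_matrix(x, arg = "x")
  Y <- if (is.matrix(y)) y else as_feature_matrix(y, arg = "y")
  R <- cs$R
  if (R < 1) abort("The canonical system has no pairs to search over.")
  Qx <- shared_basis(cs, R, side = "x", type = config$shared_basis_type)
  Qy <- if (config$y_residual_basis == "y") {
    shared_basis(cs, R, side = "y", type = config$shared_basis_type)
  } else {
    Qx
  }

  rows <- list()
  probe <- function(k) {
    Ux <- Qx[, seq_len(k), drop = FALSE]
    Uy <- Qy[, seq_len(k), drop = FALSE]
    xr <- if (k > 0) X - Ux %*% crossprod(Ux, X) else X
    yr <- if (k > 0) Y - Uy %*% crossprod(Uy, Y) else Y
    pv <- pc_variance_pair(xr, yr)
    null_x <- permutation_null_variance(pv$loading, xr, config$n_permutations,
                                        seed = child_seed(config$seed, k + 1L))
    null_y <- permutation_null_variance(pv$loading, yr, config$n_permutations,
                                        seed = child_seed(config$seed, k + R + 2L))
    cl <- classify_scenario(pv$var_x, pv$var_y, null_x, null_y,
                            level = config$significance_level,
                            gamma = config$gamma)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      k_candidate = k, scenario = cl$scenario,
      var_x = pv$var_x, var_y = pv$var_y,
      null_quantile_x = cl$null_quantile_x, null_quantile_y = cl$null_quantile_y,
      ratio = cl$ratio
    )
    cl$scenario
  }

  best_k <- 0L
  terminated_by <- "converged"

  # removing nothing may already expose case-specific-only structure (or a
  # model violation); only residual shared variation opens the search
  s0 <- probe(0L)
  if (s0 == "iv") {
    terminated_by <- "scenario_iv"
  } else if (s0 %in% c("i", "ii-ratio-pass", "iii")) {
    best_k <- 0L
  } else {
    lo <- 1L; hi <- R
    while (lo <= hi) {
      k <- as.integer((lo + hi) %/% 2)
      sc <- probe(k)
      if (sc == "iv") {
        terminated_by <- "scenario_iv"
        break
      } else if (sc %in% c("i", "ii-ratio-pass")) {
        best_k <- k
        hi <- k - 1L
      } else if (sc == "iii") {
        hi <- k - 1L
      } else { # ii: residual shared variation
        if (k == R) {
          # shared structure persists at the largest admissible k: remove it all
          terminated_by <- "exhausted"
          best_k <- R
          warn("Shared variation persists at k = min(n0, n1); removing all shared axes.")
          break
        }
        lo <- k + 1L
      }
    }
  }
  if (terminated_by == "scenario_iv" && best_k == 0L) {
    warn("Significant variation in controls but not cases at every probe; the model assumption appears violated.")
  }
  structure(
    list(
      k_selected = best_k,
      terminated_by = terminated_by,
      trace = dplyr::bind_rows(rows)
    ),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> k = %d (%s), %d probes\n",
              x$k_selected, x$terminated_by, nrow(x$trace)))
  print(x$trace)
  invisible(x)
}

#' @describeIn select_k The branch trace as a tibble.
#' @export
tidy.k_selection <- function(x, ...) x$trace

#' Fit phenotype-aware components
#'
#' The full contrastive pipeline: feature-align the two matrices, standardize
#' each by its own feature means, estimate all shared directions by
#' sample-space CCA, select the effective shared dimension k by binary search
#' with permutation nulls ([select_k()]), remove the top-k shared directions
#' from the case matrix, and return the principal components of the residual.
#' The scores of the leading components are the putative subtype gradient.
#'
#' @param x Case matrix or data frame (features x samples).
#' @param y Control matrix, same features.
#' @param config A [paca_config()].
#' @param n_components Number of residual PCs to return (default
#'   `config$max_components`, capped at the residual rank).
#'
#' @return An object of class `"paca_fit"`: `k_selection`, `shared_basis`
#'   (m x k), `x_residual`, `loadings` (m x D, orthonormal), `scores` (n1 x D),
#'   `explained_variance` (non-increasing), `canonical_correlations`, and the
#'   `config` echo.
#' @export
#' @examples
#' sim <- simulate_paca_data(sim_params(
#'   m = 150, n1 = 30, n0 = 30, k0 = 4,
#'   signal_strength = 5, seed = 2
#' ))
#' fit <- fit_paca(sim$x, sim$y, paca_config(n_permutations = 20))
#' glance(fit)
fit_paca <- function(x, y, config = paca_config(), n_components = NULL) {
  al <- check_pair(x, y)
  X <- standardize(al$x, config$standardization)
  Y <- standardize(al$y, config$standardization)
  if (config$standardization == "zscore") {
    keep <- intersect(rownames(X), rownames(Y))
    X <- X[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  m <- nrow(X); n1 <- ncol(X); n0 <- ncol(Y)
  if (m <= max(n0, n1)) {
    abort(sprintf(
      "fit_paca() requires more features than samples (m = %d <= max(n0, n1) = %d); use fit_rpaca().",
      m, max(n0, n1)
    ))
  }
  cs <- sample_space_cca(X, Y, ridge_epsilon = config$ridge_epsilon)
  ks <- select_k(X, Y, cs, config)
  U <- shared_basis(cs, ks$k_selected, side = "x", type = config$shared_basis_type)
  x_res <- residualize(X, U)

  xc <- x_res - rowMeans(x_res)
  D <- min(n_components %||% config$max_components, n1 - 1L, m)
  sv <- svd(xc, nu = D, nv = D)
  loadings <- sv$u
  for (j in seq_len(D)) {
    if (sign_of_largest(loadings[, j]) < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- crossprod(xc, loadings)
  explained <- (sv$d[seq_len(D)]^2) / (n1 - 1)
  comp <- paste0("PAC", seq_len(D))
  dimnames(loadings) <- list(rownames(X), comp)
  dimnames(scores) <- list(colnames(X), comp)

  structure(
    list(
      k_selection = ks,
      shared_basis = U,
      x_residual = x_res,
      loadings = loadings,
      scores = scores,
      explained_variance = explained,
      canonical_correlations = cs$correlations,
      config = config,
      dims = c(m = m, n1 = n1, n0 = n0)
    ),
    class = "paca_fit"
  )
}

#' @export
print.paca_fit <- function(x, ...) {
  cat(sprintf(
    "<paca_fit> %d case-specific component(s); removed k = %d shared axes (%s)\n",
    ncol(x$scores), x$k_selection$k_selected, x$k_selection$terminated_by
  ))
  cat(sprintf("  m = %d features, n1 = %d cases, n0 = %d controls\n",
              x$dims["m"], x$dims["n1"], x$dims["n0"]))
  cat("  explained variance:",
      paste(format(head(x$explained_variance, 5), digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a PACA fit
#'
#' @param x A `"paca_fit"`.
#' @param matrix Which quantity to return in long form: `"scores"` (default;
#'   one row per case sample and component), `"loadings"` (per feature and
#'   component), `"variance"` (per component), or `"trace"` (the
#'   shared-dimension search trace).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.paca_fit <- function(x, matrix = c("scores", "loadings", "variance", "trace"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = mat_to_long(x$scores, "sample_id", "component", "score"),
    loadings = mat_to_long(x$loadings, "feature_id", "component", "loading"),
    variance = tibble::tibble(
      component = colnames(x$scores),
      explained_variance = x$explained_variance
    ),
    trace = x$k_selection$trace
  )
}

#' @describeIn tidy.paca_fit One-row summary of the fit.
#' @export
glance.paca_fit <- function(x, ...) {
  tibble::tibble(
    k_selected = x$k_selection$k_selected,
    terminated_by = x$k_selection$terminated_by,
    n_features = unname(x$dims["m"]),
    n_cases = unname(x$dims["n1"]),
    n_controls = unname(x$dims["n0"]),
    n_components = ncol(x$scores),
    top_canonical_correlation = x$canonical_correlations[1],
    top_explained_variance = x$explained_variance[1]
  )
}

#' Scatter plot of the leading case-specific components
#'
#' @param object A `"paca_fit"`.
#' @param components Two component indices to plot.
#' @param labels Optional vector of sample labels (e.g. known subtypes) to
#'   color by, in score row order or named by sample ID.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paca_fit <- function(object, components = c(1, 2), labels = NULL, ...) {
  sc <- object$scores
  if (ncol(sc) < max(components)) abort("Not enough components to plot.")
  df <- tibble::tibble(
    sample_id = rownames(sc),
    c1 = sc[, components[1]],
    c2 = sc[, components[2]]
  )
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[df$sample_id]
    df$label <- factor(labels)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$c1, y = .data$c2)) +
    ggplot2::labs(
      x = colnames(sc)[components[1]],
      y = colnames(sc)[components[2]]
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$label), alpha = 0.7) +
      ggplot2::labs(color = "subtype")
  }
}

mat_to_long <- function(m, row_name, col_name, val_name) {
  tb <- feature_tbl(m, id_col = row_name)
  tidyr::pivot_longer(tb, -1, names_to = col_name, values_to = val_name)
}
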