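#' Parameters for the case/control generative model
#'
#' The simulator draws from a low-rank model in which cases and controls share
#' `k0` axes of variation while cases carry an extra, typically weak and
#' sparse, subtype axis:
#' \deqn{X = W^0 Z^0_X + W^1 Z^1_X + E_X, \qquad Y = W^0 Z^0_Y + E_Y,}
#' with Gaussian noise of standard deviation `sigma`. The columns of the shared
#' direction matrix `W^0` are orthonormal and then scaled by a decaying
#' spectrum, so some shared axes are stronger and some weaker than the subtype
#' signal; the case-specific direction `W^1` is supported on a random fraction
#' `sparsity` of the features, projected to be orthogonal to `span(W^0)` (the
#' identifiability assumption of the model), and scaled so its norm equals
#' `signal_strength` times the median shared-axis norm. The subtype score of a
#' case is its centered, scaled binary subtype label.
#'
#' @param m Number of features.
#' @param n1,n0 Number of case and control samples.
#' @param k0 Shared dimension (0 for no shared structure).
#' @param k1 Case-specific dimension; the first axis carries the subtype
#'   labels, any further axes carry standard-normal scores. Default 1.
#' @param sigma Noise standard deviation. Default 1.
#' @param signal_strength Norm of each case-specific direction relative to the
#'   median shared-axis norm; 0 gives a null dataset with no case-specific
#'   signal.
#' @param sparsity Fraction of features (in `(0, 1]`) with nonzero entries in
#'   `W^1` before the orthogonality projection.
#' @param prop Prevalence of subtype 1 among cases, in `(0, 1)`.
#' @param violation_rho Correlation in `[0, 1)` between the subtype label and
#'   the strongest shared factor; positive values violate the orthogonality
#'   assumption that case-specific and shared variation are uncorrelated. The
#'   subtype's total associated variance is held fixed: a fraction `rho^2`
#'   moves into the shared factor and the case-specific direction is scaled by
#'   `sqrt(1 - rho^2)`, so methods that remove shared variation lose power as
#'   `rho` grows.
#' @param shared_spectrum Optional length-`k0` vector of positive scales for
#'   the shared axes; the default decays geometrically from 6 to 0.5 so that
#'   the weakest shared axes straddle a unit-strength subtype signal.
#' @param seed Integer seed; the draw is fully reproducible.
#'
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(m = 400, n1 = 200, n0 = 200, k0 = 80, k1 = 1,
                       sigma = 1, signal_strength = 1, sparsity = 1,
                       prop = 0.5, violation_rho = 0,
                       shared_spectrum = NULL, seed = 1L) {
  if (sparsity <= 0 || sparsity > 1) abort("`sparsity` must lie in (0, 1].")
  if (prop <= 0 || prop >= 1) abort("`prop` must lie in (0, 1).")
  if (violation_rho < 0 || violation_rho >= 1) abort("`violation_rho` must lie in [0, 1).")
  if (signal_strength < 0) abort("`signal_strength` must be nonnegative.")
  if (k0 > 0 && is.null(shared_spectrum)) {
    shared_spectrum <- default_spectrum(k0)
  }
  if (k0 > 0 && length(shared_spectrum) != k0) {
    abort("`shared_spectrum` must have length `k0`.")
  }
  if (sparsity * m < 1) abort("`sparsity * m` must be at least 1 active feature.")
  structure(
    list(
      m = as.integer(m), n1 = as.integer(n1), n0 = as.integer(n0),
      k0 = as.integer(k0), k1 = as.integer(k1), sigma = sigma,
      signal_strength = signal_strength, sparsity = sparsity, prop = prop,
      violation_rho = violation_rho, shared_spectrum = shared_spectrum,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# Geometric decay from 6 to 0.5 (in noise-sd units): the strongest shared axes
# dominate a moderate subtype signal and the weakest sit below it.
default_spectrum <- function(k0) {
  if (k0 == 1) return(6)
  6 * (0.5 / 6)^((seq_len(k0) - 1) / (k0 - 1))
}

#' Simulate case and control matrices with known subtype structure
#'
#' Draws `(X, Y)` from the low-rank shared/case-specific model described in
#' [sim_params()], together with the generative ground truth, which the
#' calibration and power experiments score against.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `x`, `y` (tibbles; first column `feature_id`,
#'   one column per sample) and `truth`, a list carrying `subtype_labels`
#'   (named 0/1 vector over case samples), `W0`, `W1`, `Z0_x`, `Z0_y`, `Z1_x`,
#'   `k0_true`, and the `params` echo.
#' @export
#' @examples
#' sim <- simulate_paca_data(sim_params(m = 100, n1 = 20, n0 = 20, k0 = 5, seed = 7))
#' dim(as_feature_matrix(sim$x))
simulate_paca_data <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  feature_ids <- paste0("feature_", seq_len(p$m))
  case_ids <- paste0("case_", seq_len(p$n1))
  control_ids <- paste0("control_", seq_len(p$n0))

  # shared directions: orthonormal columns scaled by the decaying spectrum
  if (p$k0 > 0) {
    W0n <- qr.Q(qr(matrix(rnorm(p$m * p$k0), p$m, p$k0)))
    W0 <- sweep(W0n, 2, p$shared_spectrum, "*")
    Z0x <- matrix(rnorm(p$k0 * p$n1), p$k0, p$n1)
    Z0y <- matrix(rnorm(p$k0 * p$n0), p$k0, p$n0)
  } else {
    W0n <- matrix(0, p$m, 0); W0 <- W0n
    Z0x <- matrix(0, 0, p$n1); Z0y <- matrix(0, 0, p$n0)
  }

  # subtype labels; force both subtypes to be present
  labels <- rbinom(p$n1, 1, p$prop)
  if (length(unique(labels)) == 1) {
    flip <- sample.int(p$n1, 1)
    labels[flip] <- 1 - labels[flip]
  }
  z_subtype <- as.numeric(scale(labels))

  # Orthogonality violation: the subtype's expression is partitioned between
  # the strongest shared factor and the case-specific axis. Mixing the subtype
  # score into the shared factor gives corr(label, factor 1) = rho; scaling the
  # case-specific direction by sqrt(1 - rho^2) (below) keeps the total
  # subtype-associated variance fixed, so larger rho means less of the signal
  # is unique to cases and removable methods lose power.
  if (p$violation_rho > 0 && p$k0 > 0) {
    Z0x[1, ] <- p$violation_rho * z_subtype +
      sqrt(1 - p$violation_rho^2) * as.numeric(scale(Z0x[1, ]))
  }

  # case-specific directions: sparse support, orthogonal to span(W0), scaled
  # relative to the median shared-axis norm
  base_scale <- if (p$k0 > 0) stats::median(p$shared_spectrum) else 1
  W1 <- matrix(0, p$m, p$k1)
  Z1x <- matrix(0, p$k1, p$n1)
  if (p$signal_strength > 0 && p$k1 > 0) {
    n_active <- ceiling(p$sparsity * p$m)
    for (j in seq_len(p$k1)) {
      w <- numeric(p$m)
      support <- sample.int(p$m, n_active)
      w[support] <- rnorm(n_active)
      if (p$k0 > 0) w <- w - W0n %*% crossprod(W0n, w)
      w <- w / sqrt(sum(w^2))
      W1[, j] <- w * p$signal_strength * base_scale *
        sqrt(1 - p$violation_rho^2)
    }
    Z1x[1, ] <- z_subtype
    if (p$k1 > 1) {
      Z1x[-1, ] <- matrix(rnorm((p$k1 - 1) * p$n1), p$k1 - 1, p$n1)
    }
  }

  X <- W0 %*% Z0x + W1 %*% Z1x + matrix(rnorm(p$m * p$n1, sd = p$sigma), p$m, p$n1)
  Y <- W0 %*% Z0y + matrix(rnorm(p$m * p$n0, sd = p$sigma), p$m, p$n0)
  dimnames(X) <- list(feature_ids, case_ids)
  dimnames(Y) <- list(feature_ids, control_ids)

  truth <- list(
    subtype_labels = stats::setNames(labels, case_ids),
    W0 = W0, W1 = W1, Z0_x = Z0x, Z0_y = Z0y, Z1_x = Z1x,
    k0_true = p$k0, params = p
  )
  list(x = feature_tbl(X), y = feature_tbl(Y), truth = truth)
}

#' Simulation grid for the power experiment
#'
#' A factorial grid over subtype signal strength, signal sparsity, and subtype
#' imbalance, at a fixed problem size. The `"full"` preset uses 1000 cases,
#' 1000 controls, 2000 features and a shared dimension of 400 (cluster-scale);
#' the `"desk"` preset scales all four down by a factor of five (200/200/400/80),
#' preserving the samples-to-features and shared-dimension ratios so the same
#' qualitative regimes appear at a fraction of the cost. Strength levels and
#' sparsity values are package reconstructions of weak/moderate/strong regimes.
#'
#' @param scale `"desk"` (default) or `"full"`.
#' @param sparsity Sparsity levels of the grid.
#' @param strengths Named signal-strength levels.
#' @param props Subtype-1 prevalence levels.
#' @return A tibble with one row per grid cell and columns `m`, `n1`, `n0`,
#'   `k0`, `strength_label`, `signal_strength`, `sparsity`, `prop`.
#' @export
power_grid <- function(scale = c("desk", "full"),
                           sparsity = c(0.01, 0.05, 0.1, 0.25, 0.5, 1.0),
                           strengths = c(weak = 0.75, moderate = 1.5, strong = 5),
                           props = c(0.5, 0.25, 0.1)) {
  scale <- match.arg(scale)
  size <- if (scale == "full") {
    list(m = 2000L, n1 = 1000L, n0 = 1000L, k0 = 400L)
  } else {
    list(m = 400L, n1 = 200L, n0 = 200L, k0 = 80L)
  }
  grid <- tidyr::expand_grid(
    strength_label = names(strengths),
    sparsity = sparsity,
    prop = props
  )
  dplyr::mutate(
    grid,
    signal_strength = unname(strengths[.data$strength_label]),
    m = size$m, n1 = size$n1, n0 = size$n0, k0 = size$k0,
    .before = 1
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> m = %d, n1 = %d, n0 = %d, k0 = %d, k1 = %d\n",
    x$m, x$n1, x$n0, x$k0, x$k1
  ))
  cat(sprintf(
    "  sigma = %g, signal_strength = %g, sparsity = %g, prop = %g, violation_rho = %g, seed = %d\n",
    x$sigma, x$signal_strength, x$sparsity, x$prop, x$violation_rho, x$seed
  ))
  invisible(x)
}
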