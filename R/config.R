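#' Analysis configuration
#'
#' Bundles the tuning parameters shared by the fitting functions.
#'
#' @param gamma Positive variance-ratio threshold used when both the cases and
#'   the controls show significant variation along a candidate component: if
#'   the case variance exceeds `gamma` times the control variance the component
#'   is treated as case-specific. Default 10.
#' @param n_permutations Number of loading permutations for the per-step
#'   variance null in the shared-dimension search (>= 10). Default 100.
#' @param significance_level One-sided empirical level for calling a projection
#'   variance significant against its permutation null. Default 0.05.
#' @param seed Integer seed from which all randomness in a fit flows.
#' @param max_components Number of case-specific components to return.
#' @param standardization Feature-wise preprocessing applied to each matrix
#'   separately before the analysis: `"center"` (default), `"zscore"`, or
#'   `"none"`. Centering each group by its own feature means keeps case/control
#'   mean shifts, which are not subphenotypic structure, out of the CCA.
#' @param ridge_epsilon Nonnegative ridge added to the sample Gram matrices
#'   before inversion; `NULL` (default) uses `1e-8 * trace(S)/n` per side.
#'   An explicit `0` disables the ridge and errors on singular Gram matrices.
#' @param y_residual_basis Which representation of the shared directions is
#'   used to residualize the control matrix during the shared-dimension search:
#'   `"y"` (default; the controls' own image of the shared axes) or `"x"`.
#' @param shared_basis_type `"orthonormal"` (default) re-orthonormalizes the
#'   case-side shared directions before residualization; `"raw"` uses them as
#'   returned by the CCA.
#'
#' @return A list of class `"paca_config"`.
#' @export
paca_config <- function(gamma = 10,
                        n_permutations = 100,
                        significance_level = 0.05,
                        seed = 1L,
                        max_components = 10L,
                        standardization = c("center", "zscore", "none"),
                        ridge_epsilon = NULL,
                        y_residual_basis = c("y", "x"),
                        shared_basis_type = c("orthonormal", "raw")) {
  standardization <- match.arg(standardization)
  y_residual_basis <- match.arg(y_residual_basis)
  shared_basis_type <- match.arg(shared_basis_type)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a single positive number.")
  }
  if (!is.numeric(n_permutations) || n_permutations < 10) {
    abort("`n_permutations` must be >= 10.")
  }
  if (!is.numeric(significance_level) || significance_level <= 0 ||
      significance_level >= 1) {
    abort("`significance_level` must lie in (0, 1).")
  }
  if (!is.null(ridge_epsilon) &&
      (!is.numeric(ridge_epsilon) || ridge_epsilon < 0)) {
    abort("`ridge_epsilon` must be NULL or a nonnegative number.")
  }
  structure(
    list(
      gamma = gamma,
      n_permutations = as.integer(n_permutations),
      significance_level = significance_level,
      seed = as.integer(seed),
      max_components = as.integer(max_components),
      standardization = standardization,
      ridge_epsilon = ridge_epsilon,
      y_residual_basis = y_residual_basis,
      shared_basis_type = shared_basis_type
    ),
    class = "paca_config"
  )
}

#' @export
print.paca_config <- function(x, ...) {
  cat("<paca_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]] %||% "auto")))
  }
  invisible(x)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483587)
}
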