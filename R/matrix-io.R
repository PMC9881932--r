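#' Coerce a feature-by-sample table to a numeric matrix
#'
#' All model-fitting functions in pacar operate on feature-by-sample numeric
#' matrices (features in rows, samples in columns). This helper accepts either
#' such a matrix (with row and column names) or a data frame whose first column
#' holds feature identifiers and whose remaining columns are one numeric column
#' per sample, and returns a validated numeric matrix.
#'
#' @param x A numeric matrix or a data frame (first column = feature IDs).
#' @param role Optional role label, `"target"` (cases) or `"background"`
#'   (controls), attached as the `"role"` attribute.
#' @param arg Name used in error messages.
#'
#' @return A numeric matrix with unique feature IDs as row names and sample IDs
#'   as column names. At least one feature and two samples are required, and no
#'   missing values are allowed.
#' @export
#' @examples
#' tb <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(1, 2), s2 = c(3, 4))
#' as_feature_matrix(tb)
as_feature_matrix <- function(x, role = NULL, arg = "x") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      abort(sprintf("`%s` must have a feature-ID column plus at least one sample column.", arg))
    }
    ids <- as.character(x[[1]])
    vals <- x[, -1, drop = FALSE]
    non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    if (length(non_num) > 0) {
      abort(sprintf(
        "`%s`: non-numeric sample column(s): %s.", arg,
        paste(non_num, collapse = ", ")
      ))
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) rownames(m) <- paste0("feature_", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("sample_", seq_len(ncol(m)))
  } else {
    abort(sprintf("`%s` must be a matrix or data frame, not %s.", arg, class(x)[1]))
  }
  validate_feature_matrix(m, arg = arg)
  if (!is.null(role)) {
    role <- match.arg(role, c("target", "background"))
    attr(m, "role") <- role
  }
  m
}

validate_feature_matrix <- function(m, arg = "x") {
  if (nrow(m) < 1 || ncol(m) < 2) {
    abort(sprintf("`%s` must have at least 1 feature and 2 samples (got %d x %d).",
                  arg, nrow(m), ncol(m)))
  }
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup) > 0) {
    abort(sprintf("`%s`: duplicated feature ID(s): %s.", arg,
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s`: duplicated sample IDs.", arg))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`%s` contains missing values (first at feature '%s', sample '%s'). Impute upstream or use load_matrix(impute = TRUE).",
      arg, rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  invisible(m)
}

#' Convert a feature-by-sample matrix back to a tibble
#'
#' @param m A numeric matrix with feature IDs as row names.
#' @param id_col Name of the feature-ID column in the output.
#' @return A tibble with the feature-ID column first and one column per sample.
#' @export
feature_tbl <- function(m, id_col = "feature_id") {
  tb <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(tb, !!id_col := rownames(m), .before = 1)
}

#' Read a feature-by-sample matrix from delimited text
#'
#' Expects a header row of sample IDs and a first column of feature IDs; the
#' delimiter is auto-detected (tab or comma). Malformed numeric cells raise an
#' error locating the offending cell; duplicated feature IDs are rejected.
#' Missing values are rejected by default, or replaced with the feature (row)
#' mean when `impute = TRUE`.
#'
#' @param path Path to a TSV/CSV file.
#' @param role `"target"` (cases) or `"background"` (controls); attached as an
#'   attribute on the returned matrix.
#' @param impute Replace missing values with per-feature means?
#'
#' @return A numeric feature-by-sample matrix (see [as_feature_matrix()]).
#' @export
load_matrix <- function(path, role = c("target", "background"), impute = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  delim <- if (n_tab >= n_com) "\t" else ","
  # parse problems are inspected explicitly below; silence readr's hint
  tb <- suppressWarnings(readr::read_delim(path, delim = delim,
    col_types = readr::cols(
      readr::col_character(), .default = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(tb)
  probs <- probs[!grepl("columns", probs$expected), , drop = FALSE]
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "Malformed numeric cell in %s at line %d, column %d (expected %s, got '%s').",
      path, p$row, p$col, p$expected, p$actual
    ))
  }
  if (impute) {
    vals <- as.matrix(tb[, -1, drop = FALSE])
    if (anyNA(vals)) {
      mu <- rowMeans(vals, na.rm = TRUE)
      idx <- which(is.na(vals), arr.ind = TRUE)
      vals[idx] <- mu[idx[, 1]]
      inform(sprintf("Imputed %d missing cell(s) with feature means.", nrow(idx)))
    }
    rownames(vals) <- as.character(tb[[1]])
    return(as_feature_matrix(vals, role = role, arg = path))
  }
  as_feature_matrix(tb, role = role, arg = path)
}

#' @rdname load_matrix
#' @export
read_matrix <- load_matrix

#' Write a feature-by-sample matrix to delimited text
#'
#' @param x Matrix or data frame accepted by [as_feature_matrix()].
#' @param path Output path.
#' @param delim Field delimiter (tab by default).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delim = "\t") {
  m <- as_feature_matrix(x)
  readr::write_delim(feature_tbl(m), path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Restrict two matrices to their common features
#'
#' Cases and controls must be measured on the same features in the same order
#' before any contrastive analysis. The intersection is taken in the feature
#' order of `x`, so the operation is deterministic and idempotent.
#'
#' @param x,y Feature-by-sample matrices or data frames.
#' @return A list with elements `x` and `y`, both restricted to the common
#'   features in identical order.
#' @export
align_features <- function(x, y) {
  mx <- as_feature_matrix(x, arg = "x")
  my <- as_feature_matrix(y, arg = "y")
  common <- rownames(mx)[rownames(mx) %in% rownames(my)]
  if (length(common) == 0) {
    abort("`x` and `y` share no features; cannot align.")
  }
  list(x = mx[common, , drop = FALSE], y = my[common, , drop = FALSE])
}

#' Standardize features of a matrix
#'
#' Feature-wise (row-wise) centering or z-scoring across samples. Under
#' `"zscore"`, constant features are dropped with a warning since they carry no
#' variation and cannot be scaled.
#'
#' @param x Matrix or data frame accepted by [as_feature_matrix()].
#' @param mode `"center"` (default), `"zscore"`, or `"none"`.
#' @return A numeric matrix of the same shape (possibly fewer rows under
#'   `"zscore"`).
#' @export
standardize <- function(x, mode = c("center", "zscore", "none")) {
  mode <- match.arg(mode)
  m <- as_feature_matrix(x)
  if (mode == "none") return(m)
  m <- m - rowMeans(m)
  if (mode == "zscore") {
    s <- apply(m, 1, sd)
    const <- s < .Machine$double.eps^0.5
    if (any(const)) {
      warn(sprintf("Dropping %d constant feature(s) under zscore standardization.",
                   sum(const)))
      m <- m[!const, , drop = FALSE]
      s <- s[!const]
    }
    m <- m / s
  }
  m
}

# Shared-feature and disjoint-sample checks used by the fitting front ends.
check_pair <- function(x, y) {
  al <- align_features(x, y)
  overlap <- intersect(colnames(al$x), colnames(al$y))
  if (length(overlap) > 0) {
    abort(sprintf(
      "Sample ID(s) present in both cases and controls: %s. A sample cannot be both.",
      paste(head(overlap, 5), collapse = ", ")
    ))
  }
  al
}
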