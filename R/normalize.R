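#' Counts-per-target normalization
#'
#' Rescales each cell (row) so its total equals `target` (counts per ten
#' thousand by default). All-zero cells are returned as zero rows rather
#' than raising, so degenerate synthetic inputs flow through pipelines.
#'
#' @param counts matrix or sparse Matrix of non-negative values,
#'   cells x genes.
#' @param target positive scalar row total after scaling.
#' @return a matrix of the same class family as the input.
#' @export
cpm_normalize <- function(counts, target = 1e4) {
  check_nonneg(counts)
  totals <- Matrix::rowSums(counts)
  scale <- ifelse(totals > 0, target / totals, 0)
  if (inherits(counts, "sparseMatrix")) {
    Matrix::Diagonal(x = scale) %*% counts
  } else {
    counts * scale
  }
}

#' Log-10k normalization
#'
#' The standard single-cell transform: rescale each cell to 10,000 total
#' counts, then apply log(1 + x) (natural log). For every cell with a
#' positive total, `sum(expm1(row))` equals 10,000 exactly (up to floating
#' point); all-zero cells map to zero rows.
#'
#' @param counts matrix or sparse Matrix of non-negative values,
#'   cells x genes.
#' @return a matrix of normalized expression values.
#' @export
normalize_log10k <- function(counts) {
  check_nonneg(counts)
  x <- cpm_normalize(counts, target = 1e4)
  if (inherits(x, "sparseMatrix")) {
    x@x <- log1p(x@x)
    x
  } else {
    log1p(x)
  }
}

check_nonneg <- function(counts) {
  if (nrow(counts) < 1 || ncol(counts) < 1) {
    abort("counts must have at least one cell and one gene",
          class = "scbench_validation_error")
  }
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && min(vals) < 0) {
    abort("counts must be non-negative", class = "scbench_validation_error")
  }
  invisible(counts)
}

# Ensure a dataset carries the shared log-10k layer (computed once by the
# task harness so methods and metrics see the same values).
ensure_log10k <- function(ds) {
  if (is.null(ds$layers[["log10k"]])) {
    ds$layers[["log10k"]] <- normalize_log10k(ds$counts)
  }
  ds
}
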