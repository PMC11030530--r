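#' Annotated cell-by-gene dataset
#'
#' The container every task operates on: an integer UMI count matrix
#' (cells x genes) with per-cell and per-gene metadata, named layers of the
#' same shape, named embeddings (cells x d), named cell-cell pair graphs,
#' a free-form ground-truth store read only by metrics and positive
#' controls, and a free-form unstructured store (`uns`) for auxiliary
#' inputs such as ligand-receptor catalogues and method outputs that are
#' not matrices.
#'
#' @param counts integer matrix or sparse Matrix, cells in rows, genes in
#'   columns. Entries must be non-negative integers.
#' @param cell_meta data frame with one row per cell; a `cell_id` column is
#'   added when absent. Optional columns used by tasks: `label` (cell type),
#'   `batch`.
#' @param gene_meta data frame with one row per gene; a `gene_id` column is
#'   added when absent.
#' @param layers named list of matrices, each with the shape of `counts`.
#' @param embeddings named list of matrices with `n_cells` rows.
#' @param pairgraphs named list of non-negative cells x cells matrices.
#' @param truth named list; task ground truth.
#' @param uns named list; auxiliary unstructured data.
#'
#' @return An object of class `cbg_dataset`.
#' @export
cbg_dataset <- function(counts, cell_meta = NULL, gene_meta = NULL,
                        layers = list(), embeddings = list(),
                        pairgraphs = list(), truth = list(), uns = list()) {
  counts <- pack_matrix(counts)
  n_cells <- nrow(counts)
  n_genes <- ncol(counts)
  if (is.null(cell_meta)) {
    cell_meta <- tibble(cell_id = paste0("cell_", seq_len(n_cells)))
  }
  cell_meta <- as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta$cell_id <- paste0("cell_", seq_len(nrow(cell_meta)))
  }
  if (is.null(gene_meta)) {
    gene_meta <- tibble(gene_id = paste0("gene_", seq_len(n_genes)))
  }
  gene_meta <- as_tibble(gene_meta)
  if (!"gene_id" %in% names(gene_meta)) {
    gene_meta$gene_id <- paste0("gene_", seq_len(nrow(gene_meta)))
  }
  ds <- structure(
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
         layers = layers, embeddings = embeddings, pairgraphs = pairgraphs,
         truth = truth, uns = uns),
    class = "cbg_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a cell-by-gene dataset against its invariants
#'
#' Checks that counts are non-negative integers, metadata row counts match
#' the matrix, every layer has the shape of the counts, every embedding has
#' one row per cell, and every pair graph is a non-negative cells x cells
#' matrix. Called by the constructor and by [read_dataset()].
#'
#' @param ds a `cbg_dataset`.
#' @return `ds`, invisibly.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "cbg_dataset"))
  counts <- ds$counts
  n_cells <- nrow(counts)
  n_genes <- ncol(counts)
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && (min(vals) < 0 || !is_wholenumber(vals))) {
    abort("counts must contain non-negative integers", class = "scbench_validation_error")
  }
  if (nrow(ds$cell_meta) != n_cells) {
    abort(sprintf("cell_meta has %d rows but counts has %d cells",
                  nrow(ds$cell_meta), n_cells),
          class = "scbench_validation_error")
  }
  if (nrow(ds$gene_meta) != n_genes) {
    abort(sprintf("gene_meta has %d rows but counts has %d genes",
                  nrow(ds$gene_meta), n_genes),
          class = "scbench_validation_error")
  }
  for (nm in names(ds$layers)) {
    l <- ds$layers[[nm]]
    if (!all(dim(l) == c(n_cells, n_genes))) {
      abort(sprintf("layer '%s' has shape %dx%d, expected %dx%d",
                    nm, nrow(l), ncol(l), n_cells, n_genes),
            class = "scbench_validation_error")
    }
  }
  for (nm in names(ds$embeddings)) {
    e <- ds$embeddings[[nm]]
    if (nrow(e) != n_cells) {
      abort(sprintf("embedding '%s' has %d rows, expected %d", nm, nrow(e), n_cells),
            class = "scbench_validation_error")
    }
  }
  for (nm in names(ds$pairgraphs)) {
    g <- ds$pairgraphs[[nm]]
    if (!all(dim(g) == c(n_cells, n_cells))) {
      abort(sprintf("pairgraph '%s' is not %dx%d", nm, n_cells, n_cells),
            class = "scbench_validation_error")
    }
    gx <- if (inherits(g, "sparseMatrix")) g@x else as.numeric(g)
    if (length(gx) && min(gx) < 0) {
      abort(sprintf("pairgraph '%s' has negative entries", nm),
            class = "scbench_validation_error")
    }
  }
  invisible(ds)
}

#' Number of cells / genes in a dataset
#' @param ds a `cbg_dataset`.
#' @return integer scalar.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' Subset a dataset to a set of cells
#'
#' Subsets counts, metadata, layers, embeddings and pair graphs
#' consistently. Truth and uns stores are carried over unchanged.
#'
#' @param ds a `cbg_dataset`.
#' @param cells integer or logical index over cells.
#' @return a `cbg_dataset`.
#' @export
subset_cells <- function(ds, cells) {
  idx <- seq_len(n_cells(ds))[cells]
  cbg_dataset(
    counts = ds$counts[idx, , drop = FALSE],
    cell_meta = ds$cell_meta[idx, , drop = FALSE],
    gene_meta = ds$gene_meta,
    layers = map(ds$layers, function(l) l[idx, , drop = FALSE]),
    embeddings = map(ds$embeddings, function(e) e[idx, , drop = FALSE]),
    pairgraphs = map(ds$pairgraphs, function(g) g[idx, idx, drop = FALSE]),
    truth = ds$truth, uns = ds$uns
  )
}

#' @export
print.cbg_dataset <- function(x, ...) {
  cat(sprintf("<cbg_dataset> %d cells x %d genes\n", n_cells(x), n_genes(x)))
  meta_cols <- setdiff(names(x$cell_meta), "cell_id")
  if (length(meta_cols)) cat("  cell_meta:", paste(meta_cols, collapse = ", "), "\n")
  if (length(x$layers)) cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (length(x$embeddings)) cat("  embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  if (length(x$pairgraphs)) cat("  pairgraphs:", paste(names(x$pairgraphs), collapse = ", "), "\n")
  if (length(x$truth)) cat("  truth:", paste(names(x$truth), collapse = ", "), "\n")
  if (length(x$uns)) cat("  uns:", paste(names(x$uns), collapse = ", "), "\n")
  invisible(x)
}
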