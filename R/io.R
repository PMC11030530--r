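# Serialization of cbg_dataset to the two supported on-disk formats:
#   * h5ad  — the HDF5 annotated-matrix layout (X, layers/, obs, var,
#             obsm/, obsp/, uns/) used across the single-cell ecosystem.
#   * mtx_dir — Matrix Market counts (genes-as-rows on disk, 10x
#             convention) plus headered CSV metadata and JSON stores.

# encoding-version strings the anndata on-disk spec pins per element type
H5AD_ENC_VERSIONS <- c(
  "array" = "0.2.0", "string-array" = "0.2.0", "dataframe" = "0.2.0",
  "csr_matrix" = "0.1.0", "csc_matrix" = "0.1.0", "dict" = "0.1.0",
  "categorical" = "0.2.0"
)

#' Write a dataset to disk
#'
#' @param ds a `cbg_dataset`.
#' @param path output file (h5ad) or directory (mtx_dir).
#' @param format `"h5ad"` or `"mtx_dir"`; guessed from `path` when missing
#'   (`.h5ad` extension vs anything else).
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(ds, path, format = c("h5ad", "mtx_dir")) {
  validate_dataset(ds)
  if (length(format) > 1) {
    format <- if (grepl("\\.h5ad$", path)) "h5ad" else "mtx_dir"
  }
  format <- match.arg(format)
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    abort(sprintf("cannot write '%s': directory '%s' does not exist", path, parent),
          class = "scbench_io_error")
  }
  switch(format,
    h5ad = write_h5ad(ds, path),
    mtx_dir = write_mtx_dir(ds, path)
  )
  invisible(path)
}

#' Read a dataset from disk
#'
#' Reads files produced by [write_dataset()]; for h5ad, also understands
#' dense, CSR and CSC matrices and categorical metadata columns written by
#' other tools using the same layout.
#'
#' @param path file (h5ad) or directory (mtx_dir).
#' @param format `"h5ad"` or `"mtx_dir"`; guessed when missing.
#' @return a validated `cbg_dataset`.
#' @export
read_dataset <- function(path, format = c("h5ad", "mtx_dir")) {
  if (length(format) > 1) {
    format <- if (grepl("\\.h5ad$", path) && !dir.exists(path)) "h5ad" else "mtx_dir"
  }
  format <- match.arg(format)
  if (format == "h5ad" && !file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "scbench_io_error")
  }
  if (format == "mtx_dir" && !dir.exists(path)) {
    abort(sprintf("directory not found: '%s'", path), class = "scbench_io_error")
  }
  switch(format,
    h5ad = read_h5ad(path),
    mtx_dir = read_mtx_dir(path)
  )
}

# ---------------------------------------------------------------- h5ad ----

h5_set_attr <- function(file, obj, name, value, scalar = length(value) == 1) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, oid, name,
                          variableLengthString = is.character(value),
                          asScalar = scalar)
}

h5_mark <- function(file, obj, type) {
  h5_set_attr(file, obj, "encoding-type", type)
  h5_set_attr(file, obj, "encoding-version",
              unname(H5AD_ENC_VERSIONS[type]) %||% "0.1.0")
}

# 2D datasets are transposed on write so the on-disk dims are
# (n_obs, n_var) as the h5ad layout requires.
h5_write_dense <- function(x, file, name) {
  x <- as_dense(x)
  rhdf5::h5write(t(x), file, name)
  h5_mark(file, name, "array")
}

h5_write_sparse <- function(x, file, name) {
  tx <- methods::as(methods::as(Matrix::t(x), "generalMatrix"), "CsparseMatrix")
  rhdf5::h5createGroup(file, name)
  rhdf5::h5write(tx@x, file, paste0(name, "/data"))
  rhdf5::h5write(tx@i, file, paste0(name, "/indices"))
  rhdf5::h5write(tx@p, file, paste0(name, "/indptr"))
  h5_mark(file, name, "csr_matrix")
  h5_set_attr(file, name, "shape", as.integer(dim(x)), scalar = FALSE)
}

h5_write_matrix <- function(x, file, name) {
  if (inherits(x, "sparseMatrix")) h5_write_sparse(x, file, name)
  else h5_write_dense(x, file, name)
}

h5_write_column <- function(x, file, name) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) {
    rhdf5::h5write(as.integer(x), file, name)
    h5_mark(file, name, "array")
    h5_set_attr(file, name, "scbench-bool", 1L)
  } else if (is.character(x)) {
    rhdf5::h5write(x, file, name, variableLengthString = TRUE)
    h5_mark(file, name, "string-array")
  } else {
    rhdf5::h5write(x, file, name)
    h5_mark(file, name, "array")
  }
}

h5_write_df <- function(df, file, name, index_col) {
  rhdf5::h5createGroup(file, name)
  idx <- as.character(df[[index_col]])
  rhdf5::h5write(idx, file, paste0(name, "/_index"), variableLengthString = TRUE)
  h5_mark(file, paste0(name, "/_index"), "string-array")
  # the id column is written as data too, so column-order is never empty
  for (cn in names(df)) {
    h5_write_column(df[[cn]], file, paste0(name, "/", cn))
  }
  h5_mark(file, name, "dataframe")
  h5_set_attr(file, name, "_index", "_index")
  h5_set_attr(file, name, "column-order", names(df), scalar = FALSE)
  h5_set_attr(file, name, "scbench-index-name", index_col)
}

h5_write_value <- function(x, file, name) {
  if (inherits(x, "cbg_dataset")) {
    rhdf5::h5createGroup(file, name)
    h5_mark(file, name, "dict")
    h5_set_attr(file, name, "scbench-class", "cbg_dataset")
    h5_write_body(x, file, name)
  } else if (is.data.frame(x)) {
    x <- as_tibble(x)
    if (!".row" %in% names(x)) x$.row <- paste0("r", seq_len(nrow(x)))
    h5_write_df(x, file, name, ".row")
  } else if (is.matrix(x) || inherits(x, "Matrix")) {
    h5_write_matrix(x, file, name)
    if (!is.null(colnames(x))) {
      h5_set_attr(file, name, "scbench-colnames", colnames(x), scalar = FALSE)
    }
  } else if (is.list(x)) {
    rhdf5::h5createGroup(file, name)
    h5_mark(file, name, "dict")
    for (nm in names(x)) h5_write_value(x[[nm]], file, paste0(name, "/", nm))
  } else {
    nms <- names(x)
    x <- unname(x)
    h5_write_column(x, file, name)
    if (length(x) == 1 && is.numeric(x)) {
      h5_set_attr(file, name, "scbench-scalar", 1L)
    }
    if (!is.null(nms)) h5_set_attr(file, name, "scbench-names", nms, scalar = FALSE)
  }
}

# Writes X/layers/obs/var/obsm/obsp/uns below `root` ("" for the file root).
h5_write_body <- function(ds, file, root) {
  p <- function(x) if (nzchar(root)) paste0(root, "/", x) else x
  h5_write_matrix(ds$counts, file, p("X"))
  h5_write_df(ds$cell_meta, file, p("obs"), "cell_id")
  h5_write_df(ds$gene_meta, file, p("var"), "gene_id")
  rhdf5::h5createGroup(file, p("layers"))
  for (nm in names(ds$layers)) h5_write_matrix(ds$layers[[nm]], file, p(paste0("layers/", nm)))
  rhdf5::h5createGroup(file, p("obsm"))
  for (nm in names(ds$embeddings)) h5_write_dense(ds$embeddings[[nm]], file, p(paste0("obsm/", nm)))
  rhdf5::h5createGroup(file, p("obsp"))
  for (nm in names(ds$pairgraphs)) {
    h5_write_sparse(Matrix::Matrix(as_dense(ds$pairgraphs[[nm]]), sparse = TRUE),
                    file, p(paste0("obsp/", nm)))
  }
  rhdf5::h5createGroup(file, p("uns"))
  uns <- ds$uns
  if (length(ds$truth)) uns$truth <- ds$truth
  for (nm in names(uns)) h5_write_value(uns[[nm]], file, p(paste0("uns/", nm)))
}

write_h5ad <- function(ds, path) {
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot create '%s'", path), class = "scbench_io_error")
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_write_body(ds, path, "")
  h5_set_attr(path, "/", "encoding-type", "anndata")
  h5_set_attr(path, "/", "encoding-version", "0.1.0")
  invisible(path)
}

h5_attrs <- function(file, name) {
  tryCatch(rhdf5::h5readAttributes(file, name), error = function(e) list())
}

h5_read_matrix <- function(file, name, contents) {
  at <- h5_attrs(file, name)
  enc <- at[["encoding-type"]] %||% ""
  if (enc %in% c("csr_matrix", "csc_matrix")) {
    data <- as.numeric(rhdf5::h5read(file, paste0(name, "/data")))
    indices <- as.integer(rhdf5::h5read(file, paste0(name, "/indices")))
    indptr <- as.integer(rhdf5::h5read(file, paste0(name, "/indptr")))
    shape <- as.integer(at[["shape"]])
    if (enc == "csr_matrix") {
      m <- Matrix::t(methods::new("dgCMatrix", x = data, i = indices, p = indptr,
                                  Dim = rev(shape)))
    } else {
      m <- methods::new("dgCMatrix", x = data, i = indices, p = indptr, Dim = shape)
    }
    m
  } else {
    x <- rhdf5::h5read(file, name)
    t(as.matrix(x))
  }
}

h5_read_column <- function(file, name) {
  at <- h5_attrs(file, name)
  enc <- at[["encoding-type"]] %||% ""
  if (enc == "categorical") {
    # categorical written by other tools: categories + 0-based codes
    cats <- as.character(rhdf5::h5read(file, paste0(name, "/categories")))
    codes <- as.integer(rhdf5::h5read(file, paste0(name, "/codes")))
    return(ifelse(codes < 0, NA_character_, cats[codes + 1L]))
  }
  x <- rhdf5::h5read(file, name)
  if (is.array(x)) x <- as.vector(x)
  if (is.raw(x)) x <- as.integer(x)
  if (is.factor(x)) x <- as.character(x)
  if (inherits(x, "integer64")) x <- as.numeric(x)
  if (!is.null(at[["scbench-bool"]])) x <- as.logical(as.integer(x))
  x
}

h5_children <- function(listing, root) {
  prefix <- if (nzchar(root)) paste0("/", root) else ""
  rows <- listing[listing$group == ifelse(nzchar(prefix), prefix, "/"), , drop = FALSE]
  rows$name
}

h5_read_df <- function(file, name, listing, default_index = "cell_id") {
  at <- h5_attrs(file, name)
  index_ds <- at[["_index"]] %||% "_index"
  index_name <- at[["scbench-index-name"]] %||% default_index
  cols <- h5_children(listing, name)
  idx <- as.character(h5_read_column(file, paste0(name, "/", index_ds)))
  df <- tibble(!!index_name := idx)
  order_attr <- at[["column-order"]]
  ordered <- if (!is.null(order_attr) && length(order_attr)) as.character(order_attr) else setdiff(cols, index_ds)
  for (cn in ordered) {
    if (cn %in% cols) df[[cn]] <- h5_read_column(file, paste0(name, "/", cn))
  }
  df
}

h5_read_value <- function(file, name, listing) {
  at <- h5_attrs(file, name)
  enc <- at[["encoding-type"]] %||% ""
  is_group <- any(listing$group == paste0("/", name))
  if (identical(at[["scbench-class"]], "cbg_dataset")) {
    return(h5_read_body(file, name, listing))
  }
  if (enc == "dataframe") {
    df <- h5_read_df(file, name, listing)
    if (".row" %in% names(df)) df$.row <- NULL
    return(df)
  }
  if (enc %in% c("csr_matrix", "csc_matrix")) {
    m <- h5_read_matrix(file, name, listing)
    if (!is.null(at[["scbench-colnames"]])) colnames(m) <- as.character(at[["scbench-colnames"]])
    return(m)
  }
  if (enc == "dict" || is_group) {
    kids <- h5_children(listing, name)
    out <- list()
    for (k in kids) out[[k]] <- h5_read_value(file, paste0(name, "/", k), listing)
    return(out)
  }
  x <- rhdf5::h5read(file, name)
  if (is.array(x) && length(dim(x)) == 2) {
    m <- t(as.matrix(x))
    if (!is.null(at[["scbench-colnames"]])) colnames(m) <- as.character(at[["scbench-colnames"]])
    return(m)
  }
  x <- h5_read_column(file, name)
  if (!is.null(at[["scbench-scalar"]])) x <- x[[1]]
  if (!is.null(at[["scbench-names"]])) names(x) <- as.character(at[["scbench-names"]])
  x
}

h5_read_body <- function(file, root, listing) {
  p <- function(x) if (nzchar(root)) paste0(root, "/", x) else x
  counts <- h5_read_matrix(file, p("X"), listing)
  cell_meta <- h5_read_df(file, p("obs"), listing)
  gene_meta <- h5_read_df(file, p("var"), listing, default_index = "gene_id")
  layers <- list()
  for (nm in h5_children(listing, p("layers"))) {
    layers[[nm]] <- h5_read_matrix(file, p(paste0("layers/", nm)), listing)
  }
  embeddings <- list()
  for (nm in h5_children(listing, p("obsm"))) {
    embeddings[[nm]] <- as_dense(h5_read_matrix(file, p(paste0("obsm/", nm)), listing))
  }
  pairgraphs <- list()
  for (nm in h5_children(listing, p("obsp"))) {
    pairgraphs[[nm]] <- h5_read_matrix(file, p(paste0("obsp/", nm)), listing)
  }
  uns <- list()
  for (nm in h5_children(listing, p("uns"))) {
    uns[[nm]] <- h5_read_value(file, p(paste0("uns/", nm)), listing)
  }
  truth <- uns$truth %||% list()
  uns$truth <- NULL
  cbg_dataset(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
              layers = layers, embeddings = embeddings, pairgraphs = pairgraphs,
              truth = truth, uns = uns)
}

read_h5ad <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  listing <- rhdf5::h5ls(path)
  h5_read_body(path, "", listing)
}

# ------------------------------------------------------------- mtx_dir ----

write_mtx_dir <- function(ds, path) {
  dir.create(path, showWarnings = FALSE)
  # genes-as-rows orientation on disk (10x convention)
  Matrix::writeMM(Matrix::Matrix(Matrix::t(ds$counts), sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  utils::write.csv(ds$cell_meta, file.path(path, "cells.csv"), row.names = FALSE)
  utils::write.csv(ds$gene_meta, file.path(path, "genes.csv"), row.names = FALSE)
  if (length(ds$layers)) {
    dir.create(file.path(path, "layers"), showWarnings = FALSE)
    for (nm in names(ds$layers)) {
      Matrix::writeMM(Matrix::Matrix(Matrix::t(Matrix::Matrix(as_dense(ds$layers[[nm]]))), sparse = TRUE),
                      file.path(path, "layers", paste0(nm, ".mtx")))
    }
  }
  if (length(ds$embeddings)) {
    dir.create(file.path(path, "embeddings"), showWarnings = FALSE)
    for (nm in names(ds$embeddings)) {
      utils::write.csv(as.data.frame(as_dense(ds$embeddings[[nm]])),
                       file.path(path, "embeddings", paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (length(ds$pairgraphs)) {
    dir.create(file.path(path, "pairgraphs"), showWarnings = FALSE)
    for (nm in names(ds$pairgraphs)) {
      Matrix::writeMM(Matrix::Matrix(as_dense(ds$pairgraphs[[nm]]), sparse = TRUE),
                      file.path(path, "pairgraphs", paste0(nm, ".mtx")))
    }
  }
  jsonlite::write_json(encode_store(ds$truth), file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(encode_store(ds$uns), file.path(path, "uns.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_mm_numeric <- function(f) {
  m <- methods::as(Matrix::readMM(f), "CsparseMatrix")
  if (!methods::is(m, "dMatrix")) m <- m * 1  # pattern/logical -> numeric
  m
}

read_mtx_dir <- function(path) {
  mtx_path <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx_path)) {
    abort(sprintf("no matrix.mtx in '%s'", path), class = "scbench_io_error")
  }
  counts <- Matrix::t(read_mm_numeric(mtx_path))
  cell_meta <- as_tibble(utils::read.csv(file.path(path, "cells.csv"),
                                         stringsAsFactors = FALSE))
  gene_meta <- as_tibble(utils::read.csv(file.path(path, "genes.csv"),
                                         stringsAsFactors = FALSE))
  if (nrow(cell_meta) != nrow(counts) || nrow(gene_meta) != ncol(counts)) {
    abort(sprintf(
      "matrix is %d cells x %d genes but metadata has %d cells / %d genes",
      nrow(counts), ncol(counts), nrow(cell_meta), nrow(gene_meta)),
      class = "scbench_validation_error")
  }
  read_named_dir <- function(sub, reader) {
    d <- file.path(path, sub)
    out <- list()
    if (dir.exists(d)) {
      for (f in list.files(d)) {
        out[[sub("\\.(mtx|csv)$", "", f)]] <- reader(file.path(d, f))
      }
    }
    out
  }
  layers <- read_named_dir("layers", function(f) Matrix::t(read_mm_numeric(f)))
  embeddings <- read_named_dir("embeddings", function(f) {
    m <- as.matrix(utils::read.csv(f))
    dimnames(m) <- NULL
    m
  })
  pairgraphs <- read_named_dir("pairgraphs", read_mm_numeric)
  truth <- decode_store(jsonlite::read_json(file.path(path, "truth.json")))
  uns <- decode_store(jsonlite::read_json(file.path(path, "uns.json")))
  cbg_dataset(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
              layers = layers, embeddings = embeddings, pairgraphs = pairgraphs,
              truth = truth, uns = uns)
}

# Tagged JSON encoding for the free-form truth/uns stores.
encode_store <- function(x) {
  if (inherits(x, "cbg_dataset")) {
    return(list(`_type` = "cbg_dataset",
                counts = encode_store(as_dense(x$counts)),
                cell_meta = encode_store(as.data.frame(x$cell_meta)),
                gene_meta = encode_store(as.data.frame(x$gene_meta)),
                layers = encode_store(map(x$layers, as_dense)),
                embeddings = encode_store(map(x$embeddings, as_dense)),
                pairgraphs = encode_store(map(x$pairgraphs, as_dense)),
                truth = encode_store(x$truth),
                uns = encode_store(x$uns)))
  }
  if (is.matrix(x) || inherits(x, "Matrix")) {
    x <- as_dense(x)
    return(list(`_type` = "matrix", nrow = nrow(x), ncol = ncol(x),
                colnames = colnames(x), rownames = rownames(x),
                values = as.numeric(x)))
  }
  if (is.data.frame(x)) {
    return(list(`_type` = "data.frame",
                columns = map(as.list(x), encode_store)))
  }
  if (is.list(x)) {
    return(list(`_type` = "list", items = map(x, encode_store)))
  }
  list(`_type` = "vector", class = class(x)[1], names = names(x),
       values = unname(x), scalar = length(x) == 1)
}

decode_store <- function(x) {
  if (is.null(x) || is.null(x[["_type"]])) {
    if (is.list(x) && length(x) == 0) return(list())
    return(x)
  }
  switch(x[["_type"]],
    cbg_dataset = cbg_dataset(
      counts = decode_store(x$counts),
      cell_meta = decode_store(x$cell_meta),
      gene_meta = decode_store(x$gene_meta),
      layers = map(x$layers$items %||% list(), decode_store),
      embeddings = map(x$embeddings$items %||% list(), decode_store),
      pairgraphs = map(x$pairgraphs$items %||% list(), decode_store),
      truth = decode_store(x$truth),
      uns = decode_store(x$uns)),
    matrix = {
      m <- matrix(as.numeric(unlist(x$values)), nrow = x$nrow, ncol = x$ncol)
      if (!is.null(x$colnames)) colnames(m) <- as.character(unlist(x$colnames))
      if (!is.null(x$rownames)) rownames(m) <- as.character(unlist(x$rownames))
      m
    },
    data.frame = as_tibble(map(x$columns, decode_store)),
    list = map(x$items, decode_store),
    vector = {
      v <- unlist(x$values)
      v <- switch(x$class,
                  integer = as.integer(v),
                  numeric = as.numeric(v),
                  logical = as.logical(v),
                  character = as.character(v),
                  v)
      if (!is.null(x$names)) names(v) <- as.character(unlist(x$names))
      v
    },
    x
  )
}
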