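# Batch integration across three output formats. Methods may return a
# corrected expression matrix (layers[["corrected"]]), an embedding
# (embeddings[["X_emb"]]) or a neighbourhood graph
# (pairgraphs[["connectivities"]]); converters move results down the chain
# matrix -> embedding -> graph so one metric pair evaluates all three
# subtasks.

#' Downward format converters
#'
#' `bi_to_embedding()`: top-30 PCs of the corrected matrix written to
#' `embeddings[["X_emb"]]` (no-op when an embedding already exists).
#' `bi_to_graph()`: symmetrized binary k-NN connectivity graph (Euclidean
#' on X_emb, zero diagonal) written to `pairgraphs[["connectivities"]]`.
#' Both are deterministic given their input.
#'
#' @param ds dataset with a corrected matrix or embedding.
#' @param k neighbourhood size.
#' @return the converted dataset.
#' @export
bi_to_embedding <- function(ds) {
  if (!is.null(ds$embeddings[["X_emb"]])) return(ds)
  if (is.null(ds$layers[["corrected"]])) {
    abort("nothing to convert: no corrected matrix or embedding",
          class = "scbench_validation_error")
  }
  ds$embeddings[["X_emb"]] <- pca_scores(ds$layers[["corrected"]], 30)
  ds
}

#' @rdname bi_to_embedding
#' @export
bi_to_graph <- function(ds, k = 15) {
  if (!is.null(ds$pairgraphs[["connectivities"]])) return(ds)
  ds <- bi_to_embedding(ds)
  W <- knn_adjacency(as_dense(ds$embeddings[["X_emb"]]),
                     min(k, n_cells(ds) - 1L))
  ds$pairgraphs[["connectivities"]] <- pack_matrix(W)
  ds
}

bi_check_input <- function(ds) {
  if (is.null(ds$cell_meta[["batch"]]) || is.null(ds$cell_meta[["label"]])) {
    abort("batch and label columns required", class = "scbench_validation_error")
  }
  if (is.null(ds$layers[["log10k"]])) {
    abort("log-10k layer missing", class = "scbench_validation_error")
  }
  invisible(ds)
}

#' Batch integration controls
#'
#' Negative control: PCA embedding of the unintegrated log-10k matrix.
#' Positive control: a one-hot cell-type indicator matrix plus
#' N(0, jitter^2) noise as the embedding — batch-free and label-perfect
#' by construction.
#'
#' @param ds dataset with batches and labels.
#' @param jitter sd of the Gaussian jitter.
#' @param seed integer seed.
#' @return the dataset with `embeddings[["X_emb"]]` set.
#' @export
bi_control_no_integration <- function(ds) {
  bi_check_input(ds)
  ds$embeddings[["X_emb"]] <- pca_scores(ds$layers[["log10k"]], 30)
  ds
}

#' @rdname bi_control_no_integration
#' @export
bi_control_perfect_embedding <- function(ds, jitter = 0.01, seed = NULL) {
  bi_check_input(ds)
  labs <- factor(ds$cell_meta$label)
  onehot <- stats::model.matrix(~ labs - 1)
  with_seed_opt(seed, {
    ds$embeddings[["X_emb"]] <- onehot +
      jitter * matrix(stats::rnorm(length(onehot)), nrow = nrow(onehot))
  })
  ds
}

#' Matrix-level batch correction methods
#'
#' `bi_method_batch_centering()`: per batch, center and unit-scale each
#' gene of the log-10k matrix, then restore the global per-gene mean and
#' scale (single-cell batches are centered only, with a warning).
#' `bi_method_regress_out()`: per gene, the residual of log-10k after
#' removing a batch-indicator least-squares fit, plus the global gene
#' mean. Both write `layers[["corrected"]]`.
#'
#' @param ds dataset with batches and a log-10k layer.
#' @return the dataset with a corrected matrix.
#' @export
bi_method_batch_centering <- function(ds) {
  bi_check_input(ds)
  x <- as_dense(ds$layers[["log10k"]])
  batches <- ds$cell_meta$batch
  gmean <- colMeans(x)
  gsd <- apply(x, 2, stats::sd)
  gsd[gsd == 0] <- 1
  out <- x
  for (b in unique(batches)) {
    idx <- which(batches == b)
    xb <- x[idx, , drop = FALSE]
    mu <- colMeans(xb)
    if (length(idx) > 1) {
      sd_b <- apply(xb, 2, stats::sd)
      sd_b[sd_b == 0] <- 1
      out[idx, ] <- sweep(sweep(xb, 2, mu), 2, sd_b, "/")
    } else {
      warn(sprintf("batch '%s' has a single cell; centering only", b))
      out[idx, ] <- sweep(xb, 2, mu)
    }
  }
  ds$layers[["corrected"]] <- sweep(sweep(out, 2, gsd, "*"), 2, gmean, "+")
  ds
}

#' @rdname bi_method_batch_centering
#' @export
bi_method_regress_out <- function(ds) {
  bi_check_input(ds)
  x <- as_dense(ds$layers[["log10k"]])
  batches <- factor(ds$cell_meta$batch)
  gmean <- colMeans(x)
  if (nlevels(batches) < 2) {
    ds$layers[["corrected"]] <- x
    return(ds)
  }
  design <- stats::model.matrix(~ batches)
  fit <- stats::lm.fit(design, x)
  ds$layers[["corrected"]] <- fit$residuals +
    matrix(gmean, nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
  ds
}

#' Batch integration metrics
#'
#' `bi_metric_mixing_entropy()`: mean over cells of the Shannon entropy of
#' the batch composition among the cell's graph neighbours, normalized by
#' log(n_batches); 1 = perfectly mixed, 0 = all neighbours same-batch.
#' `bi_metric_celltype_silhouette()`: mean silhouette width of cells
#' grouped by label on the embedding, rescaled to \[0, 1\] via (s + 1)/2.
#' Missing formats are produced through the converter chain.
#'
#' @param ds dataset with a graph/embedding (or convertible matrix).
#' @param k neighbourhood size when the graph must be built.
#' @return a single real.
#' @export
bi_metric_mixing_entropy <- function(ds, k = 15) {
  batches <- ds$cell_meta[["batch"]]
  if (is.null(batches) || length(unique(batches)) < 2) {
    abort("mixing entropy needs >= 2 batches",
          class = "scbench_configuration_error")
  }
  ds <- bi_to_graph(ds, k)
  W <- as_dense(ds$pairgraphs[["connectivities"]])
  nb <- length(unique(batches))
  ent <- vapply(seq_len(nrow(W)), function(i) {
    nn <- which(W[i, ] > 0)
    if (!length(nn)) return(0)
    p <- table(batches[nn]) / length(nn)
    p <- p[p > 0]
    -sum(p * log(p)) / log(nb)
  }, numeric(1))
  mean(ent)
}

#' @rdname bi_metric_mixing_entropy
#' @export
bi_metric_celltype_silhouette <- function(ds) {
  labs <- ds$cell_meta[["label"]]
  if (is.null(labs) || length(unique(labs)) < 2) {
    abort("silhouette needs >= 2 labels", class = "scbench_validation_error")
  }
  ds <- bi_to_embedding(ds)
  sil <- cluster::silhouette(as.integer(factor(labs)),
                             stats::dist(as_dense(ds$embeddings[["X_emb"]])))
  (mean(sil[, "sil_width"]) + 1) / 2
}

bi_api_check <- function(ds, stage) {
  if (stage == "dataset") {
    bi_check_input(ds)
  } else {
    if (is.null(ds$layers[["corrected"]]) && is.null(ds$embeddings[["X_emb"]]) &&
        is.null(ds$pairgraphs[["connectivities"]])) {
      abort("method must output a corrected matrix, embedding or graph",
            class = "scbench_validation_error")
    }
  }
  invisible(ds)
}

bi_dataset_fn <- function(test_mode, seed) {
  cfg <- synthetic_config(
    n_cells = if (test_mode) 300 else 1000,
    n_genes = if (test_mode) 150 else 400,
    seed = seed)
  ds <- make_celltype_counts(cfg)
  ds <- add_batch_effect(ds, n_batches = cfg$n_batches,
                         batch_strength = cfg$batch_strength,
                         seed = child_seed(seed, 2))
  ensure_log10k(ds)
}

#' The batch integration subtasks
#'
#' Three task specs sharing methods and metrics through the downward
#' converter chain: methods output at the subtask's level (corrected
#' matrix, embedding, or graph) and the two metrics evaluate the graph
#' (batch mixing entropy) and the embedding (cell-type silhouette).
#'
#' @param level output format of the subtask.
#' @return a `task_spec`.
#' @export
task_batch_integration <- function(level = c("matrix", "embedding", "graph")) {
  level <- match.arg(level)
  tname <- paste0("batch_integration_", level)
  adapt <- function(fn) {
    # run the matrix-level method, then convert down to the subtask level
    switch(level,
      matrix = fn,
      embedding = function(ds) {
        out <- bi_to_embedding(fn(ds))
        out$layers[["corrected"]] <- NULL
        out
      },
      graph = function(ds) {
        out <- bi_to_graph(bi_to_embedding(fn(ds)))
        out$layers[["corrected"]] <- NULL
        out
      })
  }
  task_spec(tname, api_check = bi_api_check) %>%
    register(dataset_def("batched_celltypes", bi_dataset_fn, tname)) %>%
    register(method_def("perfect_embedding",
                        function(ds) bi_control_perfect_embedding(ds), tname,
                        role = "positive_control")) %>%
    register(method_def("no_integration", bi_control_no_integration, tname,
                        role = "negative_control")) %>%
    register(method_def("batch_centering", adapt(bi_method_batch_centering),
                        tname)) %>%
    register(method_def("regress_out", adapt(bi_method_regress_out), tname)) %>%
    register(metric_def("batch_mixing_entropy",
                        function(ds) bi_metric_mixing_entropy(ds), tname)) %>%
    register(metric_def("celltype_silhouette", bi_metric_celltype_silhouette,
                        tname))
}
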