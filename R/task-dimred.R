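# Dimensionality reduction for 2D visualisation. The task harness computes
# the log-10k layer once; methods and metrics both consume that same layer
# (methods may not renormalize), and methods write a 2D embedding to
# embeddings[["X_2d"]]. Control-role methods are exempt from the 2D
# contract: the full-features positive control hands the entire log-10k
# matrix to the metrics.

dr_check_input <- function(ds) {
  if (is.null(ds$layers[["log10k"]])) {
    abort("log-10k layer missing (computed by the task harness)",
          class = "scbench_validation_error")
  }
  invisible(ds)
}

#' 2D embedding methods
#'
#' `dr_method_pca2()`: first two principal components of the log-10k layer
#' (centered, not scaled). `dr_method_spectral2()`: Laplacian eigenmaps —
#' the two nontrivial eigenvectors of the symmetric normalized Laplacian
#' of a symmetrized k-NN graph on the log-10k layer; if the graph is
#' disconnected, k is doubled until connected (with a warning).
#'
#' @param ds dataset with a log-10k layer.
#' @param k neighbourhood size for the graph.
#' @return the dataset with `embeddings[["X_2d"]]` set.
#' @export
dr_method_pca2 <- function(ds) {
  dr_check_input(ds)
  if (n_cells(ds) < 3) {
    abort("need at least 3 cells", class = "scbench_validation_error")
  }
  ds$embeddings[["X_2d"]] <- pca_scores(ds$layers[["log10k"]], 2)
  ds
}

#' @rdname dr_method_pca2
#' @export
dr_method_spectral2 <- function(ds, k = 15) {
  dr_check_input(ds)
  n <- n_cells(ds)
  if (n < 3) {
    abort("need at least 3 cells", class = "scbench_validation_error")
  }
  x <- as_dense(ds$layers[["log10k"]])
  k <- min(k, n - 1L)
  repeat {
    W <- knn_adjacency(x, k)
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::components(g)$no == 1 || k >= n - 1L) break
    k <- min(n - 1L, 2L * k)
    warn(sprintf("k-NN graph disconnected; increasing k to %d", k))
  }
  deg <- rowSums(W)
  dis <- 1 / sqrt(pmax(deg, .Machine$double.eps))
  L <- diag(n) - (dis * W) * rep(dis, each = n)  # D^-1/2 W D^-1/2
  ev <- eigen(L, symmetric = TRUE)
  ord <- order(ev$values)        # ascending; first is the trivial eigenvector
  coords <- ev$vectors[, ord[2:3], drop = FALSE]
  ds$embeddings[["X_2d"]] <- coords
  ds
}

# Symmetrized (max) binary k-NN adjacency with zero diagonal.
knn_adjacency <- function(x, k) {
  n <- nrow(x)
  idx <- knn_index(x, k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, idx[i, ]] <- 1
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}

#' Dimensionality reduction controls
#'
#' Negative control: i.i.d. standard normal 2D coordinates. Positive
#' control: the full log-10k matrix passed to the metrics in place of 2D
#' coordinates — the optimal-information bound (metrics accept d >= 2).
#'
#' @param ds dataset with a log-10k layer.
#' @param seed integer seed (random control).
#' @return the dataset with `embeddings[["X_2d"]]` set.
#' @export
dr_control_random_coords <- function(ds, seed = NULL) {
  dr_check_input(ds)
  with_seed_opt(seed, {
    ds$embeddings[["X_2d"]] <- matrix(stats::rnorm(2 * n_cells(ds)), ncol = 2)
  })
  ds
}

#' @rdname dr_control_random_coords
#' @export
dr_control_full_features <- function(ds) {
  dr_check_input(ds)
  ds$embeddings[["X_2d"]] <- as_dense(ds$layers[["log10k"]])
  ds
}

#' Embedding quality metrics
#'
#' `dr_metric_trustworthiness()`: the standard rank-penalty measure at
#' neighbourhood size k — for each cell, embedded neighbours that are not
#' true high-dimensional neighbours are penalized by how far down the
#' high-dimensional ranking they sit; 1 is perfect.
#' `dr_metric_distance_correlation()`: Spearman correlation between the
#' upper-triangle pairwise Euclidean distances in the high-dimensional
#' (log-10k) and embedded spaces, computed on a seeded subsample of at
#' most 1,000 cells. Both maximize and are invariant to rigid motions and
#' global scaling of the embedding.
#'
#' @param ds dataset with `embeddings[["X_2d"]]` and a log-10k layer.
#' @param k neighbourhood size.
#' @return a single real.
#' @export
dr_metric_trustworthiness <- function(ds, k = 15) {
  dr_check_input(ds)
  emb <- ds$embeddings[["X_2d"]]
  if (is.null(emb)) abort("embedding missing", class = "scbench_validation_error")
  trustworthiness_score(as_dense(ds$layers[["log10k"]]), as_dense(emb), k)
}

#' Rank-penalty trustworthiness of an embedding
#'
#' @param high high-dimensional reference matrix (rows = cells).
#' @param emb embedding with the same rows.
#' @param k neighbourhood size (`k < n/2`).
#' @return trustworthiness in (0, 1].
#' @export
trustworthiness_score <- function(high, emb, k = 15) {
  n <- nrow(high)
  if (k >= n / 2) {
    abort("k must be smaller than n/2", class = "scbench_validation_error")
  }
  dh <- euclid_dist(high); diag(dh) <- Inf
  de <- euclid_dist(emb); diag(de) <- Inf
  penalty <- 0
  for (i in seq_len(n)) {
    rank_h <- rank(dh[i, ], ties.method = "first")   # 1 = nearest
    nn_h <- which(rank_h <= k)
    nn_e <- order(de[i, ])[seq_len(k)]
    intruders <- setdiff(nn_e, nn_h)
    penalty <- penalty + sum(rank_h[intruders] - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

#' @rdname dr_metric_trustworthiness
#' @export
dr_metric_distance_correlation <- function(ds) {
  dr_check_input(ds)
  emb <- ds$embeddings[["X_2d"]]
  if (is.null(emb)) abort("embedding missing", class = "scbench_validation_error")
  high <- as_dense(ds$layers[["log10k"]])
  n <- nrow(high)
  if (n > 1000) {
    idx <- withr::with_seed(0L, sample.int(n, 1000))
    high <- high[idx, , drop = FALSE]
    emb <- emb[idx, , drop = FALSE]
  }
  dh <- as.vector(stats::dist(high))
  de <- as.vector(stats::dist(as_dense(emb)))
  stats::cor(dh, de, method = "spearman")
}

dr_api_check <- function(ds, stage) {
  if (stage == "dataset") {
    dr_check_input(ds)
  } else {
    emb <- ds$embeddings[["X_2d"]]
    if (is.null(emb) || nrow(emb) != n_cells(ds) || ncol(emb) < 2 ||
        any(!is.finite(as_dense(emb)))) {
      abort("method must write a finite embedding with >= 2 columns",
            class = "scbench_validation_error")
    }
  }
  invisible(ds)
}

#' The dimensionality reduction task
#'
#' log-10k input contract, PCA and spectral embedding methods,
#' random-coordinates and full-features controls, trustworthiness and
#' distance-correlation metrics.
#'
#' @return a `task_spec`.
#' @export
task_dimred <- function() {
  tname <- "dimensionality_reduction"
  ds_fn <- function(test_mode, seed) {
    cfg <- synthetic_config(
      n_cells = if (test_mode) 250 else 1000,
      n_genes = if (test_mode) 150 else 400,
      seed = seed)
    ensure_log10k(make_celltype_counts(cfg))
  }
  task_spec(tname, api_check = dr_api_check) %>%
    register(dataset_def("celltypes", ds_fn, tname)) %>%
    register(method_def("full_features", dr_control_full_features, tname,
                        role = "positive_control")) %>%
    register(method_def("random_coords",
                        function(ds) dr_control_random_coords(ds), tname,
                        role = "negative_control")) %>%
    register(method_def("pca2", dr_method_pca2, tname)) %>%
    register(method_def("spectral2", function(ds) dr_method_spectral2(ds), tname)) %>%
    register(metric_def("trustworthiness",
                        function(ds) dr_metric_trustworthiness(ds), tname)) %>%
    register(metric_def("distance_correlation",
                        dr_metric_distance_correlation, tname))
}
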