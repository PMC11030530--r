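# Denoising with molecular cross-validation (MCV): each observed count is
# split binomially into a train and a test pseudo-replicate; denoisers see
# only "train" and are scored against "test".

#' Molecular cross-validation split
#'
#' Per matrix entry x, draws train ~ Binomial(x, p_train) and sets
#' test = x - train, writing layers `"train"` and `"test"`. The split
#' conserves counts exactly: train + test == counts for every entry and
#' seed. `p_train` is recorded under `truth$p_train`.
#'
#' @param ds `cbg_dataset` with integer counts.
#' @param p_train probability a molecule is assigned to train, in (0, 1).
#' @param seed integer seed.
#' @return the dataset with both layers and `truth$p_train` set.
#' @export
mcv_split <- function(ds, p_train = 0.9, seed = 1L) {
  if (p_train <= 0 || p_train >= 1) {
    abort("p_train must lie strictly in (0, 1)", class = "scbench_validation_error")
  }
  counts <- as_dense(ds$counts)
  withr::with_seed(as.integer(seed), {
    train <- matrix(stats::rbinom(length(counts), size = as.vector(counts),
                                  prob = p_train),
                    nrow = nrow(counts))
  })
  ds$layers[["train"]] <- pack_matrix(train)
  ds$layers[["test"]] <- pack_matrix(counts - train)
  ds$truth$p_train <- p_train
  ds
}

dn_check_split <- function(ds) {
  if (is.null(ds$layers[["train"]]) || is.null(ds$layers[["test"]])) {
    abort("MCV split missing", class = "scbench_validation_error")
  }
  invisible(ds)
}

#' Denoising controls
#'
#' Negative control: the identity, returning the train layer unchanged.
#' Positive control: the test-layer oracle, returning the test layer
#' rescaled by p_train/(1 - p_train) — the best attainable predictor of
#' the test sample given the split, which bounds achievable loss.
#'
#' @param ds split dataset.
#' @return the dataset with layer `"denoised"` set.
#' @export
dn_control_identity <- function(ds) {
  dn_check_split(ds)
  ds$layers[["denoised"]] <- ds$layers[["train"]]
  ds
}

#' @rdname dn_control_identity
#' @export
dn_control_test_oracle <- function(ds) {
  dn_check_split(ds)
  p <- ds$truth$p_train
  ds$layers[["denoised"]] <- as_dense(ds$layers[["test"]]) * (p / (1 - p))
  ds
}

#' Denoising methods
#'
#' `dn_method_knn_smoothing()`: averages raw train counts over each cell's
#' k nearest neighbours (Euclidean on the top-30 PCs of log-10k train
#' counts; the cell itself is included in its neighbourhood).
#' `dn_method_lowrank()`: truncated SVD of log-10k(train) at the given
#' rank, inverse transform, expm1, rows rescaled to the train library
#' sizes, negatives clamped to 0.
#'
#' @param ds split dataset.
#' @param k neighbourhood size (`k = 1` is the identity).
#' @param rank SVD rank.
#' @return the dataset with layer `"denoised"` set.
#' @export
dn_method_knn_smoothing <- function(ds, k = 10) {
  dn_check_split(ds)
  if (k >= n_cells(ds)) {
    abort("k must be smaller than the number of cells",
          class = "scbench_validation_error")
  }
  train <- as_dense(ds$layers[["train"]])
  pcs <- pca_scores(normalize_log10k(train), 30)
  d <- euclid_dist(pcs)
  denoised <- matrix(0, nrow = nrow(train), ncol = ncol(train))
  for (i in seq_len(nrow(train))) {
    nn <- order(d[i, ])[seq_len(k)]  # self has distance 0: included
    denoised[i, ] <- colMeans(train[nn, , drop = FALSE])
  }
  ds$layers[["denoised"]] <- denoised
  ds
}

#' @rdname dn_method_knn_smoothing
#' @export
dn_method_lowrank <- function(ds, rank = 10) {
  dn_check_split(ds)
  train <- as_dense(ds$layers[["train"]])
  lg <- as_dense(normalize_log10k(train))
  rank <- min(rank, nrow(lg), ncol(lg))
  sv <- svd(lg, nu = rank, nv = rank)
  recon <- sv$u %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
  expr <- expm1(recon)
  expr[expr < 0] <- 0
  lib <- rowSums(train)
  rs <- rowSums(expr)
  scale <- ifelse(rs > 0, lib / rs, 0)
  ds$layers[["denoised"]] <- expr * scale
  ds
}

dn_rescaled <- function(ds) {
  dn_check_split(ds)
  den <- as_dense(ds$layers[["denoised"]])
  if (min(den) < 0) {
    abort("denoised values must be non-negative (methods must clamp)",
          class = "scbench_validation_error")
  }
  p <- ds$truth$p_train
  list(lambda = den * (1 - p) / p, test = as_dense(ds$layers[["test"]]))
}

#' Denoising losses
#'
#' Both compare the denoised train layer, rescaled by (1 - p)/p to match
#' the test layer's expected depth, against the held-out test counts.
#' `dn_metric_mse_log10k()`: mean squared difference on the log-10k scale.
#' `dn_metric_poisson_loss()`: mean over entries of lambda - y*log(lambda)
#' with lambda = rescaled denoised + 1e-6. Orientation minimize.
#'
#' @param ds dataset with `"denoised"` and `"test"` layers.
#' @return a single real.
#' @export
dn_metric_mse_log10k <- function(ds) {
  r <- dn_rescaled(ds)
  a <- as_dense(normalize_log10k(r$lambda))
  b <- as_dense(normalize_log10k(r$test))
  mean((a - b)^2)
}

#' @rdname dn_metric_mse_log10k
#' @export
dn_metric_poisson_loss <- function(ds) {
  r <- dn_rescaled(ds)
  lambda <- r$lambda + 1e-6
  mean(lambda - r$test * log(lambda))
}

dn_api_check <- function(ds, stage) {
  if (stage == "dataset") {
    dn_check_split(ds)
    train <- as_dense(ds$layers[["train"]])
    test <- as_dense(ds$layers[["test"]])
    if (min(train) < 0 || min(test) < 0 ||
        !isTRUE(all.equal(train + test, as_dense(ds$counts)))) {
      abort("train/test layers must be a non-negative partition of counts",
            class = "scbench_validation_error")
    }
  } else {
    if (is.null(ds$layers[["denoised"]])) {
      abort("method must write a 'denoised' layer",
            class = "scbench_validation_error")
    }
  }
  invisible(ds)
}

#' The denoising task
#'
#' MCV-split synthetic counts, identity/test-oracle controls, k-NN
#' smoothing and low-rank reconstruction methods, log-10k MSE and Poisson
#' loss metrics (both minimize).
#'
#' @return a `task_spec`.
#' @export
task_denoising <- function() {
  tname <- "denoising"
  ds_fn <- function(test_mode, seed) {
    n_genes <- if (test_mode) 150 else 400
    # library scaled to ~0.5 UMIs per gene: with a reduced gene panel this
    # keeps the per-gene depth (and zero fraction) in the sparse regime
    # droplet-based denoising targets, rather than the per-cell total
    cfg <- synthetic_config(
      n_cells = if (test_mode) 300 else 1000,
      n_genes = n_genes,
      library_size_mean = 0.5 * n_genes,
      seed = seed)
    ds <- make_celltype_counts(cfg)
    mcv_split(ds, p_train = 0.9, seed = child_seed(seed, 2))
  }
  task_spec(tname, api_check = dn_api_check) %>%
    register(dataset_def("mcv_celltypes", ds_fn, tname)) %>%
    register(method_def("test_oracle", dn_control_test_oracle, tname,
                        role = "positive_control")) %>%
    register(method_def("identity", dn_control_identity, tname,
                        role = "negative_control")) %>%
    register(method_def("knn_smoothing",
                        function(ds) dn_method_knn_smoothing(ds), tname)) %>%
    register(method_def("lowrank", function(ds) dn_method_lowrank(ds), tname)) %>%
    register(metric_def("mse_log10k", dn_metric_mse_log10k, tname,
                        orientation = "minimize")) %>%
    register(metric_def("poisson_loss", dn_metric_poisson_loss, tname,
                        orientation = "minimize"))
}
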