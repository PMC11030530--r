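# Spatial decomposition: recover per-spot cell-type proportions from
# synthetic spot mixtures, given a labelled single-cell reference.
# Proportion matrices are n_spots x n_types, entries >= 0, rows summing
# to 1; predictions are stored under the truth-parallel key
# "proportions_pred".

check_proportions <- function(p, tol = 1e-6) {
  if (any(p < 0) || any(abs(rowSums(p) - 1) > tol)) {
    abort("proportion rows must be non-negative and sum to 1",
          class = "scbench_validation_error")
  }
  invisible(p)
}

#' NNLS reference-based decomposition
#'
#' Builds a per-type signature matrix as the mean CPM profile of the
#' reference cells of each type, then solves a non-negative least squares
#' problem per spot (CPM spot profile against the signatures) and
#' normalizes the solution to row sum 1 (an all-zero solution becomes a
#' uniform row, with a warning).
#'
#' @param spots spot dataset (reference under `uns$reference`).
#' @param reference labelled `cbg_dataset` with the same gene panel.
#' @return the spot dataset with `truth$proportions_pred` set.
#' @export
sp_method_nnls <- function(spots, reference = spots$uns$reference) {
  if (is.null(reference) || is.null(reference$cell_meta[["label"]])) {
    abort("labelled reference required", class = "scbench_validation_error")
  }
  if (!identical(reference$gene_meta$gene_id, spots$gene_meta$gene_id)) {
    abort("gene panels of spots and reference differ",
          class = "scbench_validation_error")
  }
  types <- spots$truth$type_order %||% sort(unique(reference$cell_meta$label))
  ref_cpm <- as_dense(cpm_normalize(reference$counts))
  sig <- t(vapply(types, function(tt) {
    colMeans(ref_cpm[reference$cell_meta$label == tt, , drop = FALSE])
  }, numeric(n_genes(reference))))          # n_types x n_genes
  spot_cpm <- as_dense(cpm_normalize(spots$counts))
  A <- t(sig)                               # genes x types
  pred <- t(apply(spot_cpm, 1, function(y) {
    sol <- pracma::lsqnonneg(A, y)$x
    if (sum(sol) == 0) {
      warn("all-zero NNLS solution; using a uniform row")
      rep(1 / length(types), length(types))
    } else {
      sol / sum(sol)
    }
  }))
  colnames(pred) <- types
  check_proportions(pred)
  spots$truth$proportions_pred <- pred
  spots
}

#' Spatial decomposition controls
#'
#' Negative control: Dirichlet(1, ..., 1) rows (uniform random
#' proportions). Positive control: a copy of the true proportions.
#'
#' @param spots spot dataset.
#' @param seed integer seed.
#' @return the spot dataset with `truth$proportions_pred` set.
#' @export
sp_control_random_proportions <- function(spots, seed = NULL) {
  nt <- ncol(spots$truth$proportions)
  with_seed_opt(seed, {
    p <- matrix(stats::rgamma(nrow(spots$truth$proportions) * nt, 1, 1),
                ncol = nt)
  })
  p <- p / rowSums(p)
  colnames(p) <- colnames(spots$truth$proportions)
  spots$truth$proportions_pred <- p
  spots
}

#' @rdname sp_control_random_proportions
#' @export
sp_control_true_proportions <- function(spots) {
  if (is.null(spots$truth$proportions)) {
    abort("true proportions missing", class = "scbench_validation_error")
  }
  spots$truth$proportions_pred <- spots$truth$proportions
  spots
}

#' Proportion recovery metrics
#'
#' `sp_metric_r2()`: 1 - SS_res/SS_tot over all matrix entries jointly,
#' with SS_tot about the global mean of the truth entries (maximize; can
#' be arbitrarily negative). `sp_metric_mae()`: mean absolute difference
#' (minimize). Columns are aligned by type identifier before comparison.
#'
#' @param spots spot dataset with `proportions_pred` and truth.
#' @return a single real.
#' @export
sp_metric_r2 <- function(spots) {
  pt <- sp_aligned(spots)
  ss_res <- sum((pt$pred - pt$truth)^2)
  ss_tot <- sum((pt$truth - mean(pt$truth))^2)
  1 - ss_res / ss_tot
}

#' @rdname sp_metric_r2
#' @export
sp_metric_mae <- function(spots) {
  pt <- sp_aligned(spots)
  mean(abs(pt$pred - pt$truth))
}

sp_aligned <- function(spots) {
  pred <- spots$truth$proportions_pred
  truth <- spots$truth$proportions
  if (is.null(pred)) abort("predictions missing", class = "scbench_validation_error")
  if (!all(dim(pred) == dim(truth))) {
    abort("prediction and truth shapes differ", class = "scbench_validation_error")
  }
  if (!is.null(colnames(pred)) && !is.null(colnames(truth))) {
    if (!setequal(colnames(pred), colnames(truth))) {
      abort("prediction and truth type sets differ",
            class = "scbench_validation_error")
    }
    pred <- pred[, colnames(truth), drop = FALSE]
  }
  list(pred = pred, truth = truth)
}

sp_api_check <- function(ds, stage) {
  if (stage == "dataset") {
    if (is.null(ds$truth$proportions)) {
      abort("spot dataset must carry true proportions",
            class = "scbench_validation_error")
    }
    check_proportions(ds$truth$proportions, tol = 1e-9)
  } else {
    if (is.null(ds$truth$proportions_pred)) {
      abort("method must write proportions_pred",
            class = "scbench_validation_error")
    }
    check_proportions(ds$truth$proportions_pred)
  }
  invisible(ds)
}

#' The spatial decomposition task
#'
#' Dirichlet spot mixtures over a synthetic labelled reference, NNLS
#' decomposition, random/true-proportion controls, joint-entry R2 and MAE
#' metrics.
#'
#' @return a `task_spec`.
#' @export
task_spatial_decomposition <- function() {
  tname <- "spatial_decomposition"
  ds_fn <- function(test_mode, seed) {
    cfg <- synthetic_config(
      n_cells = if (test_mode) 300 else 1000,
      n_genes = if (test_mode) 150 else 400,
      seed = seed)
    reference <- make_celltype_counts(cfg)
    make_spatial_mixture(reference,
                         n_spots = if (test_mode) 80 else 200,
                         cells_per_spot_mean = 20, dirichlet_alpha = 1,
                         seed = child_seed(seed, 2))
  }
  task_spec(tname, api_check = sp_api_check) %>%
    register(dataset_def("dirichlet_mixture", ds_fn, tname)) %>%
    register(method_def("true_proportions", sp_control_true_proportions, tname,
                        role = "positive_control")) %>%
    register(method_def("random_proportions",
                        function(ds) sp_control_random_proportions(ds), tname,
                        role = "negative_control")) %>%
    register(method_def("nnls", function(ds) sp_method_nnls(ds), tname)) %>%
    register(metric_def("r2_proportions", sp_metric_r2, tname)) %>%
    register(metric_def("mae_proportions", sp_metric_mae, tname,
                        orientation = "minimize"))
}
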