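# Label projection: predict cell-type labels of a query subset from a
# labelled reference subset of the same dataset.

#' Split a dataset into reference and query
#'
#' Either a stratified random `query_fraction` of cells per label, or
#' (with `by_batch = TRUE`) one whole batch chosen by seed. True query
#' labels are moved to `truth$labels_query` (tibble of cell_id/label) and
#' masked (`NA`) in `cell_meta$label`; the partition is recorded in
#' `cell_meta$is_query`.
#'
#' @param ds labelled `cbg_dataset`.
#' @param query_fraction fraction of cells per label in the query
#'   (ignored when `by_batch`).
#' @param by_batch hold one whole batch out as query.
#' @param seed integer seed.
#' @return the dataset with the split applied.
#' @export
split_reference_query <- function(ds, query_fraction = 0.25, by_batch = FALSE,
                                  seed = 1L) {
  labels <- ds$cell_meta[["label"]]
  if (is.null(labels)) {
    abort("labels required for a reference/query split",
          class = "scbench_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    if (by_batch) {
      batches <- ds$cell_meta[["batch"]]
      if (is.null(batches) || length(unique(batches)) < 2) {
        abort("by_batch split needs >= 2 batches",
              class = "scbench_validation_error")
      }
      held <- sample(unique(batches), 1)
      is_query <- batches == held
    } else {
      stopifnot(query_fraction > 0, query_fraction < 1)
      is_query <- rep(FALSE, length(labels))
      for (lab in unique(labels)) {
        idx <- which(labels == lab)
        nq <- round(query_fraction * length(idx))
        if (nq > 0) is_query[sample(idx, nq)] <- TRUE
      }
    }
  })
  ds$truth$labels_query <- tibble(cell_id = ds$cell_meta$cell_id[is_query],
                                  label = labels[is_query])
  ds$cell_meta$is_query <- is_query
  ds$cell_meta$label[is_query] <- NA_character_
  ds
}

lp_check_split <- function(ds) {
  if (is.null(ds$cell_meta[["is_query"]]) || is.null(ds$truth$labels_query)) {
    abort("reference/query split missing", class = "scbench_validation_error")
  }
  invisible(ds)
}

#' Label projection controls
#'
#' The positive control copies the true query labels into the prediction
#' column; the negative control samples each query prediction from the
#' reference's empirical label distribution.
#'
#' @param ds split dataset.
#' @param seed integer seed (random control).
#' @return the dataset with `cell_meta$prediction` filled for query cells.
#' @export
lp_control_true_labels <- function(ds) {
  lp_check_split(ds)
  pred <- rep(NA_character_, n_cells(ds))
  truth <- ds$truth$labels_query
  pred[match(truth$cell_id, ds$cell_meta$cell_id)] <- truth$label
  ds$cell_meta$prediction <- pred
  ds
}

#' @rdname lp_control_true_labels
#' @export
lp_control_random_labels <- function(ds, seed = NULL) {
  lp_check_split(ds)
  ref_labels <- ds$cell_meta$label[!ds$cell_meta$is_query]
  pred <- rep(NA_character_, n_cells(ds))
  with_seed_opt(seed, {
    pred[ds$cell_meta$is_query] <- sample(ref_labels,
                                          sum(ds$cell_meta$is_query),
                                          replace = TRUE)
  })
  ds$cell_meta$prediction <- pred
  ds
}

#' Label projection methods
#'
#' Both operate on log-10k features. `lp_method_logistic()` fits an
#' L2-regularized multinomial logistic regression on the reference at a
#' fixed penalty (lambda = 1/n_reference, the C = 1 convention; no
#' hyperparameter search). `lp_method_knn()` votes over the k nearest
#' reference neighbours in the top-50 principal components fitted on the
#' reference, ties broken by smallest label index.
#'
#' @param ds split dataset.
#' @param k neighbourhood size.
#' @return the dataset with `cell_meta$prediction` filled for query cells.
#' @export
lp_method_logistic <- function(ds) {
  lp_check_split(ds)
  ds <- ensure_log10k(ds)
  is_query <- ds$cell_meta$is_query
  if (!any(!is_query)) {
    abort("empty reference", class = "scbench_validation_error")
  }
  x <- as_dense(ds$layers$log10k)
  y <- factor(ds$cell_meta$label[!is_query])
  xr <- x[!is_query, , drop = FALSE]
  if (nlevels(y) < 2) {
    pred_q <- rep(levels(y), sum(is_query))
  } else {
    fit <- glmnet::glmnet(xr, y, family = "multinomial", alpha = 0,
                          lambda = 1 / nrow(xr), standardize = FALSE)
    pred_q <- as.character(stats::predict(fit, x[is_query, , drop = FALSE],
                                          type = "class"))
  }
  pred <- rep(NA_character_, n_cells(ds))
  pred[is_query] <- pred_q
  ds$cell_meta$prediction <- pred
  ds
}

#' @rdname lp_method_logistic
#' @export
lp_method_knn <- function(ds, k = 15) {
  lp_check_split(ds)
  ds <- ensure_log10k(ds)
  is_query <- ds$cell_meta$is_query
  if (!any(!is_query)) {
    abort("empty reference", class = "scbench_validation_error")
  }
  x <- as_dense(ds$layers$log10k)
  xr <- x[!is_query, , drop = FALSE]
  d <- min(50, ncol(xr), nrow(xr) - 1L)
  p <- stats::prcomp(xr, center = TRUE, scale. = FALSE, rank. = d)
  ref_pc <- p$x
  query_pc <- scale(x[is_query, , drop = FALSE], center = p$center,
                    scale = FALSE) %*% p$rotation
  ref_labels <- ds$cell_meta$label[!is_query]
  label_levels <- sort(unique(ref_labels))
  k <- min(k, nrow(ref_pc))
  dmat <- euclid_dist(query_pc, ref_pc)
  pred_q <- apply(dmat, 1, function(r) {
    nn <- order(r)[seq_len(k)]
    votes <- table(factor(ref_labels[nn], levels = label_levels))
    label_levels[which.max(votes)]  # which.max takes the smallest index on ties
  })
  pred <- rep(NA_character_, n_cells(ds))
  pred[is_query] <- pred_q
  ds$cell_meta$prediction <- pred
  ds
}

lp_pred_truth <- function(ds) {
  if (is.null(ds$cell_meta[["prediction"]])) {
    abort("predictions missing", class = "scbench_validation_error")
  }
  truth <- ds$truth$labels_query
  idx <- match(truth$cell_id, ds$cell_meta$cell_id)
  list(pred = ds$cell_meta$prediction[idx], truth = truth$label)
}

#' Label projection metrics
#'
#' `lp_metric_accuracy()`: fraction of query cells whose prediction equals
#' the true label. `lp_metric_macro_f1()`: unweighted mean over truth
#' labels of the per-label F1 score (labels never predicted get F1 = 0).
#' Both range in \[0, 1\], orientation maximize.
#'
#' @param ds dataset with predictions and a split.
#' @return a single real.
#' @export
lp_metric_accuracy <- function(ds) {
  pt <- lp_pred_truth(ds)
  mean(pt$pred == pt$truth, na.rm = FALSE)
}

#' @rdname lp_metric_accuracy
#' @export
lp_metric_macro_f1 <- function(ds) {
  pt <- lp_pred_truth(ds)
  labs <- sort(unique(pt$truth))
  f1 <- vapply(labs, function(l) {
    tp <- sum(pt$pred == l & pt$truth == l, na.rm = TRUE)
    fp <- sum(pt$pred == l & pt$truth != l, na.rm = TRUE)
    fn <- sum(pt$pred != l & pt$truth == l, na.rm = TRUE)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

lp_api_check <- function(ds, stage) {
  if (stage == "dataset") {
    lp_check_split(ds)
  } else {
    if (is.null(ds$cell_meta[["prediction"]]) ||
        any(is.na(ds$cell_meta$prediction[ds$cell_meta$is_query]))) {
      abort("method must predict a label for every query cell",
            class = "scbench_validation_error")
    }
  }
  invisible(ds)
}

#' The label projection task
#'
#' Two dataset variants (stratified random split; hold-one-batch-out),
#' two controls, logistic regression and k-NN methods, accuracy and
#' macro-F1 metrics.
#'
#' @return a `task_spec`.
#' @export
task_label_projection <- function() {
  tname <- "label_projection"
  make_ds <- function(by_batch) {
    function(test_mode, seed) {
      cfg <- synthetic_config(
        n_cells = if (test_mode) 400 else 2000,
        n_genes = if (test_mode) 150 else 500,
        seed = seed)
      ds <- make_celltype_counts(cfg)
      if (by_batch) {
        ds <- add_batch_effect(ds, n_batches = 3, batch_strength = 0.3,
                               seed = child_seed(seed, 2))
      }
      ds <- split_reference_query(ds, query_fraction = 0.25,
                                  by_batch = by_batch,
                                  seed = child_seed(seed, 3))
      ensure_log10k(ds)
    }
  }
  task_spec(tname, api_check = lp_api_check) %>%
    register(dataset_def("stratified_split", make_ds(FALSE), tname)) %>%
    register(dataset_def("batch_holdout", make_ds(TRUE), tname)) %>%
    register(method_def("true_labels", lp_control_true_labels, tname,
                        role = "positive_control")) %>%
    register(method_def("random_labels",
                        function(ds) lp_control_random_labels(ds), tname,
                        role = "negative_control")) %>%
    register(method_def("logistic_regression", lp_method_logistic, tname)) %>%
    register(method_def("knn_classifier", function(ds) lp_method_knn(ds), tname)) %>%
    register(metric_def("accuracy", lp_metric_accuracy, tname)) %>%
    register(metric_def("macro_f1", lp_metric_macro_f1, tname))
}
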