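# Matching modalities: align two views of the same cells into one latent
# space; evaluated by the fraction of samples closer than the true match
# (FOSCTTM, 0 = perfect). Methods see only the data; the pairing lives in
# the truth store and is read exclusively by the metric (and the controls,
# which are exempt by role).

mm_check <- function(pair) {
  if (!inherits(pair, "modality_pair")) {
    abort("expected a modality_pair", class = "scbench_validation_error")
  }
  invisible(pair)
}

#' Shared-feature SVD alignment
#'
#' Standardizes each modality's shared feature block per feature, fits a
#' rank-d SVD basis on the row-concatenation of the two blocks, and
#' projects each block into that basis. Component signs are fixed by
#' making each component's largest-magnitude loading positive, so the
#' embedding is deterministic given the input.
#'
#' @param pair a `modality_pair`.
#' @param d latent dimension (`<= n_shared_features`).
#' @return the pair with `embeddings$X_joint_1` / `X_joint_2` set.
#' @export
mm_method_shared_svd <- function(pair, d = 10) {
  mm_check(pair)
  ns <- pair$n_shared_features
  if (d > ns) {
    abort("d must be <= n_shared_features", class = "scbench_validation_error")
  }
  s1 <- scale(pair$X1[, seq_len(ns), drop = FALSE])
  s2 <- scale(pair$X2[, seq_len(ns), drop = FALSE])
  s1[!is.finite(s1)] <- 0
  s2[!is.finite(s2)] <- 0
  sv <- svd(rbind(s1, s2), nu = 0, nv = d)
  V <- sv$v
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, "*")
  pair$embeddings$X_joint_1 <- s1 %*% V
  pair$embeddings$X_joint_2 <- s2 %*% V
  pair
}

#' Matching modality controls
#'
#' Positive control: both modalities receive modality 1's embedding, so
#' paired cells share identical coordinates (FOSCTTM 0). Negative
#' control: both modalities embedded, then modality 2's rows permuted by
#' a seeded random permutation.
#'
#' @param pair a `modality_pair`.
#' @param seed integer seed.
#' @return the pair with joint embeddings set.
#' @export
mm_control_true_coords <- function(pair) {
  pair <- mm_method_shared_svd(pair)
  emb2 <- pair$embeddings$X_joint_1
  emb2[pair$truth$pairing, ] <- pair$embeddings$X_joint_1
  pair$embeddings$X_joint_2 <- emb2
  pair
}

#' @rdname mm_control_true_coords
#' @export
mm_control_shuffled <- function(pair, seed = NULL) {
  pair <- mm_method_shared_svd(pair)
  with_seed_opt(seed, {
    perm <- sample.int(nrow(pair$X2))
  })
  pair$embeddings$X_joint_2 <- pair$embeddings$X_joint_2[perm, , drop = FALSE]
  pair
}

#' Fraction of samples closer than the true match
#'
#' For each cell i of modality 1, the fraction of the other n - 1
#' modality-2 cells lying strictly closer (Euclidean) to i's embedding
#' than i's true match; symmetrized by averaging with the reverse
#' direction and averaged over cells. 0 is perfect, 1 fully adversarial;
#' a random pairing gives 0.5 in expectation. Ties (equidistant points)
#' count as not-closer, favouring the method. Orientation minimize.
#'
#' @param emb1,emb2 embeddings with equal row counts.
#' @param pairing integer permutation: cell i of modality 1 is truly
#'   matched to row `pairing[i]` of modality 2.
#' @return a single real in \[0, 1\].
#' @export
mm_metric_foscttm <- function(emb1, emb2, pairing) {
  n <- nrow(emb1)
  if (nrow(emb2) != n) {
    abort("embeddings must have equal row counts",
          class = "scbench_validation_error")
  }
  if (!identical(sort(as.integer(pairing)), seq_len(n))) {
    abort("pairing must be a permutation", class = "scbench_validation_error")
  }
  d12 <- euclid_dist(emb1, emb2)
  frac1 <- vapply(seq_len(n), function(i) {
    sum(d12[i, ] < d12[i, pairing[i]]) / (n - 1)
  }, numeric(1))
  inv <- integer(n)
  inv[pairing] <- seq_len(n)
  frac2 <- vapply(seq_len(n), function(j) {
    sum(d12[, j] < d12[inv[j], j]) / (n - 1)
  }, numeric(1))
  mean((frac1 + frac2) / 2)
}

mm_metric_foscttm_pair <- function(pair) {
  if (is.null(pair$embeddings$X_joint_1) || is.null(pair$embeddings$X_joint_2)) {
    abort("joint embeddings missing", class = "scbench_validation_error")
  }
  mm_metric_foscttm(pair$embeddings$X_joint_1, pair$embeddings$X_joint_2,
                    pair$truth$pairing)
}

mm_api_check <- function(pair, stage) {
  mm_check(pair)
  if (stage == "method") {
    if (is.null(pair$embeddings$X_joint_1) || is.null(pair$embeddings$X_joint_2)) {
      abort("method must embed both modalities",
            class = "scbench_validation_error")
    }
  }
  invisible(pair)
}

#' The matching modalities task
#'
#' A stub task: one linked-view dataset, shared-feature SVD alignment,
#' true-coordinates and shuffled controls, FOSCTTM metric.
#'
#' @return a `task_spec`.
#' @export
task_matching_modalities <- function() {
  tname <- "matching_modalities"
  ds_fn <- function(test_mode, seed) {
    make_paired_modalities(n_cells = if (test_mode) 300 else 500, seed = seed)
  }
  task_spec(tname, api_check = mm_api_check) %>%
    register(dataset_def("linked_gaussian", ds_fn, tname)) %>%
    register(method_def("true_coords", mm_control_true_coords, tname,
                        role = "positive_control")) %>%
    register(method_def("shuffled", function(p) mm_control_shuffled(p), tname,
                        role = "negative_control")) %>%
    register(method_def("shared_feature_svd",
                        function(p) mm_method_shared_svd(p), tname)) %>%
    register(metric_def("foscttm", mm_metric_foscttm_pair, tname,
                        orientation = "minimize"))
}
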