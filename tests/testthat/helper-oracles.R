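# Independent oracles used by several test files. Each is a deliberately
# naive implementation, kept separate from the code path it checks.

# Literal precision-recall walk.
auprc_oracle <- function(keys, truth_set) {
  n_pos <- length(truth_set)
  hits <- 0; auc <- 0; prev_recall <- 0
  for (i in seq_along(keys)) {
    hits <- hits + (keys[i] %in% truth_set)
    recall <- hits / n_pos
    if (recall > prev_recall) {
      auc <- auc + (hits / i) * (recall - prev_recall)
      prev_recall <- recall
    }
  }
  auc
}

# Double loop over cells and embedded neighbours.
trustworthiness_oracle <- function(high, emb, k) {
  n <- nrow(high)
  dh <- as.matrix(stats::dist(high)); diag(dh) <- Inf
  de <- as.matrix(stats::dist(emb)); diag(de) <- Inf
  total <- 0
  for (i in seq_len(n)) {
    rk <- rank(dh[i, ], ties.method = "first")
    emb_nn <- order(de[i, ])[seq_len(k)]
    for (j in emb_nn) {
      if (rk[j] > k) total <- total + (unname(rk[j]) - k)
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

# Two cell types with disjoint marker genes: the NNLS design is orthogonal
# and proportions follow in closed form.
orthogonal_reference <- function() {
  counts <- rbind(matrix(c(20L, 0L), 10, 2, byrow = TRUE),
                  matrix(c(0L, 20L), 10, 2, byrow = TRUE))
  ref <- cbg_dataset(counts)
  ref$cell_meta$label <- rep(c("A", "B"), each = 10)
  ref
}
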