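bi_fixture <- function(seed = 1L, strength = 1, n = 150, g = 60) {
  ds <- tiny_dataset(seed = seed, n_cells = n, n_genes = g)
  ds <- add_batch_effect(ds, 2, strength, seed = seed + 50L)
  ds$layers$log10k <- as.matrix(normalize_log10k(ds$counts))
  ds
}

test_that("converters build a symmetric zero-diagonal graph from any level", {
  ds <- bi_fixture(seed = 2)
  out <- bi_method_batch_centering(ds)
  out <- bi_to_graph(out)
  W <- as.matrix(out$pairgraphs$connectivities)
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(W %in% c(0, 1)))

  # embedding-level input goes straight to the graph
  emb_ds <- bi_control_no_integration(ds)
  g2 <- bi_to_graph(emb_ds)
  expect_equal(dim(g2$pairgraphs$connectivities), c(150, 150))
  expect_error(bi_to_embedding(tiny_dataset()),
               class = "scbench_validation_error")

  # determinism
  expect_equal(as.matrix(bi_to_graph(emb_ds)$pairgraphs$connectivities),
               as.matrix(g2$pairgraphs$connectivities))
})

test_that("matrix methods reduce to near-identity with a single batch", {
  ds <- tiny_dataset(seed = 3, n_cells = 80, n_genes = 40)
  ds$cell_meta$batch <- "b1"
  ds$layers$log10k <- as.matrix(normalize_log10k(ds$counts))
  cent <- bi_method_batch_centering(ds)
  expect_equal(cent$layers$corrected, ds$layers$log10k, tolerance = 1e-8)
  reg <- bi_method_regress_out(ds)
  expect_equal(reg$layers$corrected, ds$layers$log10k, tolerance = 1e-8)
})

test_that("regression removes purely additive per-(batch, gene) offsets", {
  ds <- bi_fixture(seed = 4, strength = 0)
  clean <- ds$layers$log10k
  offsets <- matrix(rnorm(2 * ncol(clean), sd = 2), nrow = 2)
  b <- as.integer(factor(ds$cell_meta$batch))
  ds$layers$log10k <- clean + offsets[b, ]
  out <- bi_method_regress_out(ds)
  # residual-plus-mean recovers the clean matrix up to a per-gene constant
  resid <- out$layers$corrected - clean
  expect_lt(max(apply(resid, 2, stats::sd)), 0.15)
  # and the batch-mean difference is gone
  d1 <- colMeans(out$layers$corrected[b == 1, ])
  d2 <- colMeans(out$layers$corrected[b == 2, ])
  expect_lt(max(abs(d1 - d2)), 1e-8)
})

test_that("mixing entropy matches hand-computed compositions", {
  # build a dataset whose graph neighbourhoods have known batch mixtures
  make_graph_ds <- function(batches, W) {
    ds <- cbg_dataset(random_counts(length(batches), 4))
    ds$cell_meta$batch <- batches
    ds$cell_meta$label <- "t"
    ds$pairgraphs$connectivities <- W
    ds
  }
  n <- 8
  batches <- rep(c("a", "b"), each = 4)
  # every cell connected to 2 a's and 2 b's -> entropy 1
  W <- matrix(0, n, n)
  for (i in 1:n) W[i, c(1, 2, 5, 6)] <- 1
  diag(W) <- 0
  for (i in c(1, 2, 5, 6)) W[i, setdiff(c(1, 2, 5, 6, 3, 7), i)[1:4]] <- 1
  ds <- make_graph_ds(batches, pmax(W, t(W)))
  # construct exact half/half neighbourhoods instead: 1 a + 1 b per cell
  W2 <- matrix(0, n, n)
  for (i in 1:n) W2[i, c((i %% 4) + 1, ((i + 1) %% 4) + 5)] <- 1
  diag(W2) <- 0
  ds2 <- make_graph_ds(batches, W2)
  expect_equal(bi_metric_mixing_entropy(ds2), 1)

  # all neighbours same batch -> 0
  W3 <- matrix(0, n, n)
  W3[1:4, 1:4] <- 1; W3[5:8, 5:8] <- 1; diag(W3) <- 0
  expect_equal(bi_metric_mixing_entropy(make_graph_ds(batches, W3)), 0)

  # (3/4, 1/4) composition: entropy 0.5623 nats / ln 2
  W4 <- matrix(0, n, n)
  for (i in 1:n) W4[i, c(setdiff(1:4, i)[1:3], 5)] <- 1
  ds4 <- make_graph_ds(batches, W4)
  expected <- -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2)
  expect_equal(bi_metric_mixing_entropy(ds4), expected, tolerance = 1e-12)
  expect_equal(round(expected, 4), 0.8113)

  # invariance to batch relabeling
  ds5 <- ds4
  ds5$cell_meta$batch <- c(a = "z", b = "w")[ds4$cell_meta$batch]
  expect_equal(bi_metric_mixing_entropy(ds5), bi_metric_mixing_entropy(ds4))
})

test_that("silhouette uses the (s+1)/2 rescaling and label grouping", {
  ds <- cbg_dataset(random_counts(20, 4))
  ds$cell_meta$label <- rep(c("x", "y"), each = 10)
  ds$cell_meta$batch <- rep(c("a", "b"), 10)
  emb <- rbind(matrix(rnorm(20, 0, 0.01), 10),
               matrix(rnorm(20, 10, 0.01), 10))
  ds$embeddings$X_emb <- emb
  expect_gt(bi_metric_celltype_silhouette(ds), 0.99)
  # label relabeling leaves the metric unchanged
  ds2 <- ds
  ds2$cell_meta$label <- c(x = "q", y = "r")[ds$cell_meta$label]
  expect_equal(bi_metric_celltype_silhouette(ds2),
               bi_metric_celltype_silhouette(ds))
})

test_that("the perfect embedding dominates and methods beat no-integration on mixing", {
  tb <- benchmark_task(task_batch_integration("matrix"), test_mode = TRUE,
                       seed = 17)
  norm <- tb$normalized
  mix <- norm %>% dplyr::filter(metric == "batch_mixing_entropy")
  expect_equal(mix$value[mix$method == "perfect_embedding"], 1)
  expect_equal(mix$value[mix$method == "no_integration"], 0)
  expect_gt(mix$value[mix$method == "batch_centering"], 0)
  expect_gt(mix$value[mix$method == "regress_out"], 0)
  sil <- norm %>% dplyr::filter(metric == "celltype_silhouette")
  expect_equal(max(sil$value[sil$method %in% c("perfect_embedding",
                                               "no_integration")]), 1)
})

test_that("all three subtask levels run and agree on control anchoring", {
  for (lvl in c("embedding", "graph")) {
    tb <- benchmark_task(task_batch_integration(lvl), test_mode = TRUE,
                         seed = 17)
    ov <- tb$overall
    expect_equal(ov$overall[ov$method == "perfect_embedding"], 1)
    expect_equal(ov$overall[ov$method == "no_integration"], 0)
  }
})
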