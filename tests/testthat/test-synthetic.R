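test_that("generators are pure functions of config and seed", {
  cfg <- tiny_config(seed = 9)
  d1 <- make_celltype_counts(cfg)
  d2 <- make_celltype_counts(cfg)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$cell_meta$label, d2$cell_meta$label)
  d3 <- make_celltype_counts(tiny_config(seed = 10))
  expect_false(identical(as.matrix(d1$counts), as.matrix(d3$counts)))
})

test_that("de_strength 0 removes cell-type structure", {
  ds <- make_celltype_counts(tiny_config(seed = 2, de_strength = 0,
                                         n_cells = 600, n_genes = 80))
  lg <- as.matrix(normalize_log10k(ds$counts))
  tm <- rowsum(lg, ds$cell_meta$label) /
    as.vector(table(ds$cell_meta$label))
  # per-type mean profiles agree up to sampling noise
  spread <- apply(tm, 2, function(col) diff(range(col)))
  expect_lt(mean(spread), 0.15)
  expect_error(make_celltype_counts(tiny_config(n_cells = 2, n_types = 3)),
               class = "scbench_validation_error")
})

test_that("separable defaults support >0.9 linear classification accuracy", {
  ds <- make_celltype_counts(synthetic_config(n_cells = 600, n_genes = 200,
                                              seed = 4))
  ds <- split_reference_query(ds, 0.25, seed = 5)
  acc <- lp_metric_accuracy(lp_method_logistic(ds))
  expect_gt(acc, 0.9)
})

test_that("batch effects are off at strength 0 and detectable at strength 1", {
  ds <- tiny_dataset(seed = 3)
  b0 <- add_batch_effect(ds, 2, 0, seed = 7)
  expect_identical(as.matrix(b0$counts), as.matrix(ds$counts))
  expect_true(all(b0$uns$batch_factors == 1))

  big <- make_celltype_counts(tiny_config(seed = 3, n_cells = 2000,
                                          n_genes = 100))
  b1 <- add_batch_effect(big, 2, 1, seed = 7)
  # stratification: per-batch type frequencies within +-10% of global
  tab <- prop.table(table(b1$cell_meta$batch, b1$cell_meta$label), 1)
  glob <- prop.table(table(b1$cell_meta$label))
  expect_true(all(abs(sweep(tab, 2, glob)) < 0.1 * max(glob)))

  # a batch effect exists: same-batch neighbour excess on log-10k PCs
  pcs <- scbench:::pca_scores(normalize_log10k(b1$counts), 10)
  idx <- scbench:::knn_index(pcs, 15)
  same <- mean(b1$cell_meta$batch[as.vector(idx)] ==
                 rep(b1$cell_meta$batch, times = 15))
  expect_gt(same, 0.55)  # stratified expectation is ~0.5
  expect_error(add_batch_effect(ds, 0, 1), class = "scbench_validation_error")
})

test_that("spatial mixtures have row-stochastic truth and conserve counts", {
  ref <- tiny_dataset(seed = 5)
  sp <- make_spatial_mixture(ref, n_spots = 40, cells_per_spot_mean = 10,
                             seed = 6)
  expect_true(all(abs(rowSums(sp$truth$proportions) - 1) < 1e-9))
  expect_true(all(sp$truth$proportions >= 0))
  expect_equal(colnames(sp$truth$proportions), sort(unique(ref$cell_meta$label)))

  # near-zero alpha: most spots dominated by one type
  sp2 <- make_spatial_mixture(ref, n_spots = 100, cells_per_spot_mean = 10,
                              dirichlet_alpha = 0.01, seed = 8)
  expect_gt(mean(apply(sp2$truth$proportions, 1, max) > 0.9), 0.8)

  unlabelled <- cbg_dataset(random_counts(10, 5))
  expect_error(make_spatial_mixture(unlabelled, 5, 5),
               class = "scbench_validation_error")
})

test_that("paired modalities share a latent space and a feature block", {
  # d1 = d2 = shared block and zero noise: the two views coincide
  p0 <- make_paired_modalities(n_cells = 50, d_latent = 5, d1 = 8, d2 = 8,
                               n_shared_features = 8, noise_sd = 0, seed = 2)
  expect_equal(p0$X1, p0$X2)
  expect_equal(p0$truth$pairing, 1:50)

  p <- make_paired_modalities(n_cells = 300, seed = 3)  # noise_sd 0.1 default
  shared_cor <- diag(stats::cor(p$X1[, 1:p$n_shared_features],
                                p$X2[, 1:p$n_shared_features]))
  expect_true(all(shared_cor > 0.9))
  expect_error(make_paired_modalities(d_latent = 10, d1 = 5),
               class = "scbench_validation_error")
  expect_error(make_paired_modalities(d1 = 20, d2 = 20, n_shared_features = 30),
               class = "scbench_validation_error")
})

test_that("planted communication truth scales counts and stays disjoint", {
  ds <- tiny_dataset(seed = 6, n_genes = 100)
  lr <- make_lr_database(ds$gene_meta$gene_id, n_pairs = 20, seed = 7)
  expect_equal(nrow(dplyr::distinct(lr)), 20)
  expect_false(any(duplicated(c(lr$ligand, lr$receptor))))

  same <- make_ccc_truth(ds, lr, n_true_pairs = 5, effect_fold = 1, seed = 8)
  expect_identical(as.matrix(same$ds$counts), as.matrix(ds$counts))

  planted <- make_ccc_truth(ds, lr, n_true_pairs = 5, effect_fold = 20, seed = 8)
  expect_equal(nrow(dplyr::distinct(planted$truth$triples)), 5)
  expect_error(make_ccc_truth(ds, lr, n_true_pairs = 1e6),
               class = "scbench_validation_error")

  # a planted ligand is strongly up in its source type
  tr <- planted$truth$triples[1, ]
  gi <- match(tr$ligand, ds$gene_meta$gene_id)
  src <- planted$ds$cell_meta$label == tr$source
  expect_gt(mean(as.matrix(planted$ds$counts)[src, gi]),
            5 * mean(as.matrix(ds$counts)[src, gi]) )
})
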