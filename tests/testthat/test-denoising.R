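test_that("MCV splits conserve counts exactly", {
  ds <- tiny_dataset(seed = 2, n_cells = 40, n_genes = 25)
  sp <- mcv_split(ds, 0.9, seed = 3)
  expect_equal(as.matrix(sp$layers$train) + as.matrix(sp$layers$test),
               as.matrix(ds$counts))
  expect_true(all(as.matrix(sp$layers$train) >= 0))
  expect_true(all(as.matrix(sp$layers$test) >= 0))

  zero <- cbg_dataset(matrix(0L, 5, 5))
  spz <- mcv_split(zero, 0.5, seed = 1)
  expect_true(all(as.matrix(spz$layers$train) == 0))
  expect_true(all(as.matrix(spz$layers$test) == 0))
  expect_error(mcv_split(ds, 1), class = "scbench_validation_error")
  expect_error(mcv_split(ds, 0), class = "scbench_validation_error")
})

test_that("binomial split moments match at x = 1000, p = 0.9", {
  ds <- cbg_dataset(matrix(1000L, 1, 1))
  trains <- vapply(1:100, function(s) {
    as.matrix(mcv_split(ds, 0.9, seed = s)$layers$train)[1, 1]
  }, numeric(1))
  # mean of 100 draws: sd = sqrt(1000 * .9 * .1) / 10
  expect_lt(abs(mean(trains) - 900), 3 * sqrt(90) / 10 * 3)
})

test_that("controls behave as the identity and the rescaled test oracle", {
  ds <- mcv_split(tiny_dataset(seed = 4, n_cells = 30, n_genes = 20), 0.5,
                  seed = 5)
  oracle <- dn_control_test_oracle(ds)
  expect_equal(as.matrix(oracle$layers$denoised), as.matrix(ds$layers$test))
  ident <- dn_control_identity(ds)
  expect_equal(as.matrix(ident$layers$denoised), as.matrix(ds$layers$train))

  zero <- mcv_split(cbg_dataset(matrix(0L, 4, 4)), 0.5, seed = 1)
  expect_true(all(as.matrix(dn_control_identity(zero)$layers$denoised) == 0))
  expect_error(dn_control_identity(tiny_dataset()),
               class = "scbench_validation_error")
})

test_that("k-NN smoothing with k = 1 is the identity and full-rank SVD is lossless", {
  ds <- mcv_split(tiny_dataset(seed = 6, n_cells = 25, n_genes = 15), 0.9,
                  seed = 7)
  out <- dn_method_knn_smoothing(ds, k = 1)
  expect_equal(as.matrix(out$layers$denoised), as.matrix(ds$layers$train))
  expect_error(dn_method_knn_smoothing(ds, k = 25),
               class = "scbench_validation_error")

  full <- dn_method_lowrank(ds, rank = 15)
  # full rank: reconstruction equals log-10k(train), so after expm1 and
  # row rescaling the train layer itself is recovered
  expect_equal(as.matrix(full$layers$denoised), as.matrix(ds$layers$train),
               tolerance = 1e-6)
})

test_that("losses match their closed forms", {
  ds <- mcv_split(tiny_dataset(seed = 8, n_cells = 20, n_genes = 12), 0.75,
                  seed = 9)
  # denoised * (1-p)/p == test exactly -> zero MSE
  perfect <- ds
  perfect$layers$denoised <- as.matrix(ds$layers$test) * (0.75 / 0.25)
  expect_equal(dn_metric_mse_log10k(perfect), 0)

  # lambda == y == 1 everywhere -> loss 1 (up to the epsilon guard)
  unit <- mcv_split(cbg_dataset(matrix(2L, 6, 6)), 0.5, seed = 1)
  unit$layers$train <- matrix(1, 6, 6)
  unit$layers$test <- matrix(1, 6, 6)
  unit$layers$denoised <- matrix(1, 6, 6)
  expect_equal(dn_metric_poisson_loss(unit), 1, tolerance = 1e-5)

  neg <- perfect
  neg$layers$denoised <- -perfect$layers$denoised
  expect_error(dn_metric_poisson_loss(neg), class = "scbench_validation_error")
})

test_that("the Poisson loss is minimized by the mean over constant predictions", {
  ds <- mcv_split(tiny_dataset(seed = 10, n_cells = 15, n_genes = 10), 0.5,
                  seed = 11)
  y <- as.matrix(ds$layers$test)
  loss_at <- function(lam) {
    d <- ds
    d$layers$denoised <- matrix(lam, nrow(y), ncol(y))  # p = 0.5: scale 1
    dn_metric_poisson_loss(d)
  }
  opt <- stats::optimize(loss_at, c(1e-4, max(y) + 1))$minimum
  expect_equal(opt, mean(y), tolerance = 1e-2)
})

test_that("the oracle control beats the identity on Poisson loss end-to-end", {
  ds <- mcv_split(make_celltype_counts(synthetic_config(n_cells = 500,
                                                        n_genes = 150,
                                                        seed = 12)),
                  0.9, seed = 13)
  expect_lt(dn_metric_poisson_loss(dn_control_test_oracle(ds)),
            dn_metric_poisson_loss(dn_control_identity(ds)))
})

test_that("both denoisers beat the identity on Poisson loss end-to-end", {
  tb <- benchmark_task(task_denoising(), test_mode = TRUE, seed = 31)
  norm <- tb$normalized %>% dplyr::filter(metric == "poisson_loss")
  ident <- norm$value[norm$method == "identity"]
  expect_gt(norm$value[norm$method == "knn_smoothing"], ident)
  expect_gt(norm$value[norm$method == "lowrank"], ident)
})
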