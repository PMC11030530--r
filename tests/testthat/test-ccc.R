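two_type_expression <- function() {
  # type A: gene L high; type B: gene R high; gene U uniform
  counts <- rbind(
    cbind(matrix(30L, 20, 1), matrix(0L, 20, 1), matrix(10L, 20, 1)),
    cbind(matrix(0L, 20, 1), matrix(30L, 20, 1), matrix(10L, 20, 1)))
  ds <- cbg_dataset(counts,
                    gene_meta = tibble::tibble(gene_id = c("L", "R", "U")))
  ds$cell_meta$label <- rep(c("A", "B"), each = 20)
  ds$uns$lr_db <- tibble::tibble(ligand = "L", receptor = "R")
  ds
}

test_that("the magnitude score is the mean of the two cell-type means, gated", {
  ds <- two_type_expression()
  pred <- ccc_score_magnitude(ds)
  lg <- as.matrix(normalize_log10k(ds$counts))
  lA <- mean(lg[1:20, 1]); rB <- mean(lg[21:40, 2])
  ab <- pred$score[pred$source == "A" & pred$target == "B"]
  expect_equal(ab, (lA + rB) / 2)
  # ligand undetected in source type B -> gate forces 0
  ba <- pred$score[pred$source == "B" & pred$target == "A"]
  expect_equal(ba, 0)
  # target-cell ligand expression is never read: perturbing the ligand
  # column of target cells in the shared normalized layer changes nothing
  ds2 <- ds
  ds2$layers$log10k <- lg
  ds2$layers$log10k[21:40, 1] <- 5
  pred2 <- ccc_score_magnitude(ds2)
  expect_equal(pred2$score[pred2$source == "A" & pred2$target == "B"], ab)
})

test_that("absent LR genes are skipped with a warning", {
  ds <- two_type_expression()
  ds$uns$lr_db <- tibble::tibble(ligand = c("L", "ghost"),
                                 receptor = c("R", "R"))
  expect_warning(pred <- ccc_score_magnitude(ds), "absent")
  expect_true(all(pred$ligand == "L"))
})

test_that("specificity scores sit mid-null for uniform genes and top for planted ones", {
  # a gene expressed uniformly across types: its observed score is a
  # typical draw from the permutation null, so the specificity averages
  # to one half over replicate datasets
  mean_spec <- mean(vapply(1:20, function(s) {
    counts <- withr::with_seed(s, matrix(rpois(40 * 2, 10), 40))
    ds <- cbg_dataset(counts,
                      gene_meta = tibble::tibble(gene_id = c("U", "V")))
    ds$cell_meta$label <- rep(c("A", "B"), each = 20)
    ds$uns$lr_db <- tibble::tibble(ligand = "U", receptor = "V")
    spec <- ccc_score_specificity(ds, n_perm = 50, seed = s + 100L)
    mean(spec$score)
  }, numeric(1)))
  expect_gt(mean_spec, 0.35)
  expect_lt(mean_spec, 0.65)

  ds2 <- two_type_expression()
  spec2 <- ccc_score_specificity(ds2, n_perm = 100, seed = 4)
  ab <- spec2$score[spec2$source == "A" & spec2$target == "B"]
  expect_gte(ab, 100 / 101)
  # fixed seed -> identical scores
  spec3 <- ccc_score_specificity(ds2, n_perm = 100, seed = 4)
  expect_identical(spec2$score, spec3$score)
  expect_error(ccc_score_specificity(ds2, n_perm = 5),
               class = "scbench_validation_error")
})

test_that("aggregation groups and orders deterministically", {
  pred <- tibble::tibble(source = c("A", "A"), target = c("B", "B"),
                         ligand = c("l1", "l2"), receptor = c("r1", "r2"),
                         score = c(1, 3))
  m <- ccc_aggregate(pred, "mean", "source_target")
  expect_equal(m$score, 2)
  x <- ccc_aggregate(pred, "max", "source_target")
  expect_equal(x$score, 3)
  # single-row groups: mean == max
  lt_mean <- ccc_aggregate(pred, "mean", "ligand_target")
  lt_max <- ccc_aggregate(pred, "max", "ligand_target")
  expect_equal(lt_mean$score[order(lt_mean$key)],
               lt_max$score[order(lt_max$key)])
  # ligand_target grouping ignores source identity
  pred2 <- pred
  pred2$source <- c("C", "D")
  expect_equal(ccc_aggregate(pred2, "mean", "ligand_target"),
               ccc_aggregate(pred, "mean", "ligand_target"))
  expect_error(ccc_aggregate(pred[0, ], "mean", "source_target"),
               class = "scbench_validation_error")
})

test_that("AUPRC matches hand walks and the brute-force oracle", {
  expect_equal(ccc_metric_auprc(c("p1", "n1", "p2"), c("p1", "p2")),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(ccc_metric_auprc(c("p1", "p2", "n1"), c("p1", "p2")), 1)
  expect_equal(ccc_metric_auprc(c("p1", "p2"), c("p1", "p2")), 1)
  expect_error(ccc_metric_auprc(c("a"), character(0)),
               class = "scbench_validation_error")

  withr::with_seed(11, {
    for (rep in 1:100) {
      n <- sample(5:50, 1)
      keys <- paste0("k", sample(n))
      truth <- sample(keys, sample(1:n, 1))
      expect_equal(ccc_metric_auprc(keys, truth), auprc_oracle(keys, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("the odds ratio uses a ceiling(5%) bin and the Haldane correction", {
  # 100 ranked, 10 positives, 4 in the top-5 bin
  keys <- paste0("k", 1:100)
  truth <- c(keys[1:4], keys[50:55])
  expect_equal(ccc_metric_odds_ratio(keys, truth), (4 * 89) / (1 * 6))
  # a full top bin engages the correction (b = 0): all cells get +0.5
  truth2 <- c(keys[1:5], keys[50:54])
  or2 <- ccc_metric_odds_ratio(keys, truth2)
  expect_equal(or2, (5.5 * 90.5) / (0.5 * 5.5))
  expect_true(is.finite(or2) && or2 > 1)
  # rank permutations inside the bins leave the OR unchanged
  shuffled <- c(sample(keys[1:5]), sample(keys[6:100]))
  expect_equal(ccc_metric_odds_ratio(shuffled, truth),
               ccc_metric_odds_ratio(keys, truth))
  expect_error(ccc_metric_odds_ratio(keys[1:10], truth),
               class = "scbench_validation_error")
})

test_that("uniformly placed positives give an odds ratio near 1", {
  withr::with_seed(12, {
    ors <- vapply(1:200, function(i) {
      keys <- paste0("k", 1:100)
      truth <- sample(keys, 20)
      ccc_metric_odds_ratio(keys, truth)
    }, numeric(1))
  })
  expect_gt(mean(ors > 0.2 & ors < 5), 0.9)
  expect_lt(abs(median(ors) - 1), 0.75)
})

test_that("planted interactions are recovered end-to-end by magnitude scoring", {
  tb <- benchmark_task(task_ccc("source_target"), test_mode = TRUE, seed = 5)
  norm <- tb$normalized
  expect_equal(norm$value[norm$method == "oracle_ranking" &
                            norm$metric == "auprc"], 1)
  expect_equal(norm$value[norm$method == "random_ranking" &
                            norm$metric == "auprc"], 0)
  # a planted pair sits in the top 5% for the magnitude scorer
  ds <- task_ccc("source_target")$datasets[[1]]$fn(test_mode = TRUE, seed = 5)
  ranked <- ccc_aggregate(ccc_score_magnitude(ds), "max", "source_target")
  truth <- scbench:::ccc_truth_keys(ds$truth$ccc, "source_target")
  top <- ranked$key[seq_len(ceiling(0.05 * nrow(ranked)))]
  expect_gt(length(intersect(top, truth)), 0)
})
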