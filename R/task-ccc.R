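# Cell-cell communication: score ligand-receptor pairs per (source type,
# target type), aggregate to the subtask's key level (source-target or
# ligand-target) with mean or max, and evaluate the ranking against the
# planted truth with AUPRC and a top-5% odds ratio.

ccc_check_input <- function(ds) {
  if (is.null(ds$cell_meta[["label"]]) || is.null(ds$uns$lr_db)) {
    abort("labels and an LR database required", class = "scbench_validation_error")
  }
  ensure_log10k(ds)
}

# Per-type mean expression and detection fraction for a gene subset.
ccc_type_stats <- function(ds, genes) {
  labs <- ds$cell_meta$label
  types <- sort(unique(labs))
  gi <- match(genes, ds$gene_meta$gene_id)
  lg <- as_dense(ds$layers[["log10k"]])[, gi, drop = FALSE]
  det <- as_dense(ds$counts)[, gi, drop = FALSE] > 0
  means <- rowsum(lg, labs) / as.vector(table(labs)[types])
  detfrac <- rowsum(det + 0, labs) / as.vector(table(labs)[types])
  list(types = types, means = means, detfrac = detfrac, genes = genes)
}

#' Expression-magnitude ligand-receptor scoring
#'
#' For every (source type, target type, LR pair): the mean of the
#' ligand's average log-10k expression in the source type and the
#' receptor's average log-10k expression in the target type, gated to 0
#' unless both genes are detected (count > 0) in at least 10% of their
#' cell type's cells. LR pairs whose genes are absent from the panel are
#' skipped with a warning.
#'
#' @param ds labelled dataset with `uns$lr_db`.
#' @param lr_db ligand-receptor table (defaults to the one on the
#'   dataset).
#' @param detection_gate minimum detection fraction.
#' @return tibble (source, target, ligand, receptor, score).
#' @export
ccc_score_magnitude <- function(ds, lr_db = ds$uns$lr_db,
                                detection_gate = 0.1) {
  ds <- ccc_check_input(ds)
  present <- lr_db$ligand %in% ds$gene_meta$gene_id &
    lr_db$receptor %in% ds$gene_meta$gene_id
  if (any(!present)) {
    warn(sprintf("skipping %d LR pairs with genes absent from the panel",
                 sum(!present)))
    lr_db <- lr_db[present, , drop = FALSE]
  }
  genes <- unique(c(lr_db$ligand, lr_db$receptor))
  st <- ccc_type_stats(ds, genes)
  grid <- tidyr::expand_grid(source = st$types, target = st$types,
                             pair = seq_len(nrow(lr_db)))
  li <- match(lr_db$ligand[grid$pair], genes)
  ri <- match(lr_db$receptor[grid$pair], genes)
  si <- match(grid$source, st$types)
  ti <- match(grid$target, st$types)
  lmean <- st$means[cbind(si, li)]
  rmean <- st$means[cbind(ti, ri)]
  gate <- st$detfrac[cbind(si, li)] >= detection_gate &
    st$detfrac[cbind(ti, ri)] >= detection_gate
  tibble(source = grid$source, target = grid$target,
         ligand = lr_db$ligand[grid$pair], receptor = lr_db$receptor[grid$pair],
         score = ifelse(gate, (lmean + rmean) / 2, 0))
}

#' Cell-type-specificity ligand-receptor scoring
#'
#' Builds a null distribution by permuting cell-type labels `n_perm`
#' times and recomputing the ungated magnitude score for every triple.
#' The specificity score is 1 - (r + 1)/(n_perm + 1) where r is the
#' number of permutations with null >= observed (add-one-corrected
#' empirical p-value); a triple more extreme than every permutation
#' scores n_perm/(n_perm + 1).
#'
#' @inheritParams ccc_score_magnitude
#' @param n_perm number of label permutations (>= 10).
#' @param seed integer seed.
#' @return tibble (source, target, ligand, receptor, score).
#' @export
ccc_score_specificity <- function(ds, lr_db = ds$uns$lr_db, n_perm = 100,
                                  seed = NULL) {
  if (n_perm < 10) {
    abort("n_perm must be >= 10", class = "scbench_validation_error")
  }
  ds <- ccc_check_input(ds)
  present <- lr_db$ligand %in% ds$gene_meta$gene_id &
    lr_db$receptor %in% ds$gene_meta$gene_id
  if (any(!present)) {
    warn(sprintf("skipping %d LR pairs with genes absent from the panel",
                 sum(!present)))
    lr_db <- lr_db[present, , drop = FALSE]
  }
  genes <- unique(c(lr_db$ligand, lr_db$receptor))
  labs <- ds$cell_meta$label
  gi <- match(genes, ds$gene_meta$gene_id)
  lg <- as_dense(ds$layers[["log10k"]])[, gi, drop = FALSE]
  types <- sort(unique(labs))
  li <- match(lr_db$ligand, genes)
  ri <- match(lr_db$receptor, genes)
  grid <- tidyr::expand_grid(source = types, target = types,
                             pair = seq_len(nrow(lr_db)))
  si <- match(grid$source, types)
  ti <- match(grid$target, types)
  magnitude <- function(lab_vec) {
    means <- rowsum(lg, lab_vec) / as.vector(table(lab_vec)[types])
    (means[cbind(si, li[grid$pair])] + means[cbind(ti, ri[grid$pair])]) / 2
  }
  observed <- magnitude(labs)
  exceed <- integer(length(observed))
  with_seed_opt(seed, {
    for (p in seq_len(n_perm)) {
      null_scores <- magnitude(sample(labs))
      exceed <- exceed + (null_scores >= observed)
    }
  })
  tibble(source = grid$source, target = grid$target,
         ligand = lr_db$ligand[grid$pair], receptor = lr_db$receptor[grid$pair],
         score = 1 - (exceed + 1) / (n_perm + 1))
}

#' Aggregate LR scores to a subtask's key level
#'
#' Groups prediction rows by (source, target) or (ligand, target) and
#' aggregates scores with mean or max. Keys are returned sorted by
#' descending aggregated score, ties broken lexicographically so the
#' ranking is deterministic.
#'
#' @param pred tibble from a scorer.
#' @param how `"mean"` or `"max"`.
#' @param level `"source_target"` or `"ligand_target"`.
#' @return tibble (key, score), ranked.
#' @export
ccc_aggregate <- function(pred, how = c("mean", "max"),
                          level = c("source_target", "ligand_target")) {
  how <- match.arg(how)
  level <- match.arg(level)
  if (nrow(pred) == 0) {
    abort("empty prediction table", class = "scbench_validation_error")
  }
  keyed <- if (level == "source_target") {
    pred %>% mutate(key = paste(.data$source, .data$target, sep = "|"))
  } else {
    pred %>% mutate(key = paste(.data$ligand, .data$target, sep = "|"))
  }
  agg_fn <- if (how == "mean") mean else max
  keyed %>%
    group_by(.data$key) %>%
    summarise(score = agg_fn(.data$score), .groups = "drop") %>%
    arrange(desc(.data$score), .data$key)
}

ccc_truth_keys <- function(truth, level) {
  if (level == "source_target") {
    paste(truth$positive_st$source, truth$positive_st$target, sep = "|")
  } else {
    paste(truth$positive_lt$ligand, truth$positive_lt$target, sep = "|")
  }
}

#' Area under the precision-recall curve of a ranking
#'
#' Walks the ranked keys; at each positive hit adds
#' precision x delta-recall (step-wise, no interpolation). Positives
#' absent from the ranking count as never retrieved (they contribute to
#' the recall denominator only).
#'
#' @param ranked tibble (key, score) in rank order, or a character vector
#'   of keys.
#' @param truth_set character vector of positive keys (non-empty).
#' @return AUPRC in (0, 1\].
#' @export
ccc_metric_auprc <- function(ranked, truth_set) {
  if (length(truth_set) == 0) {
    abort("empty truth set", class = "scbench_validation_error")
  }
  keys <- if (is.data.frame(ranked)) ranked$key else ranked
  n_pos <- length(truth_set)
  hits <- 0
  auc <- 0
  for (i in seq_along(keys)) {
    if (keys[i] %in% truth_set) {
      hits <- hits + 1
      auc <- auc + (hits / i) * (1 / n_pos)
    }
  }
  auc
}

#' Odds ratio of true pairs in the top fraction of a ranking
#'
#' Splits the ranking at m = ceiling(top_fraction * n) and forms the 2x2
#' contingency table of positive/negative vs top/rest; the odds ratio is
#' (a d)/(b c) with the Haldane-Anscombe +0.5 correction applied to all
#' four cells when any is zero. Requires n >= 20 so the top bin is
#' non-trivial.
#'
#' @param ranked tibble (key, score) in rank order, or a character vector.
#' @param truth_set character vector of positive keys.
#' @param top_fraction fraction of the ranking in the top bin.
#' @return the odds ratio (maximize).
#' @export
ccc_metric_odds_ratio <- function(ranked, truth_set, top_fraction = 0.05) {
  keys <- if (is.data.frame(ranked)) ranked$key else ranked
  n <- length(keys)
  if (n < 20) {
    abort("ranking must contain at least 20 keys",
          class = "scbench_validation_error")
  }
  m <- ceiling(top_fraction * n)
  top <- keys[seq_len(m)]
  rest <- keys[-seq_len(m)]
  a <- sum(top %in% truth_set)
  b <- m - a
  c_ <- sum(rest %in% truth_set)
  d <- length(rest) - c_
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

# -- task assembly ---------------------------------------------------------

ccc_make_method <- function(scorer, how, level) {
  function(ds) {
    pred <- scorer(ds)
    ds$uns$ccc_ranked <- ccc_aggregate(pred, how = how, level = level)
    ds
  }
}

ccc_all_keys <- function(ds, level) {
  types <- sort(unique(ds$cell_meta$label))
  lr_db <- ds$uns$lr_db
  if (level == "source_target") {
    g <- tidyr::expand_grid(source = types, target = types)
    paste(g$source, g$target, sep = "|")
  } else {
    g <- tidyr::expand_grid(ligand = unique(lr_db$ligand), target = types)
    paste(g$ligand, g$target, sep = "|")
  }
}

ccc_control_oracle <- function(ds, level, seed = NULL) {
  truth_keys <- ccc_truth_keys(ds$truth$ccc, level)
  keys <- ccc_all_keys(ds, level)
  with_seed_opt(seed, {
    pos <- sample(intersect(keys, truth_keys))
    neg <- sample(setdiff(keys, truth_keys))
  })
  ds$uns$ccc_ranked <- tibble(key = c(pos, neg),
                              score = rev(seq_along(keys)) / length(keys))
  ds
}

ccc_control_random <- function(ds, level, seed = NULL) {
  keys <- ccc_all_keys(ds, level)
  with_seed_opt(seed, {
    keys <- sample(keys)
  })
  ds$uns$ccc_ranked <- tibble(key = keys,
                              score = rev(seq_along(keys)) / length(keys))
  ds
}

ccc_api_check <- function(ds, stage) {
  if (stage == "dataset") {
    if (is.null(ds$truth$ccc) || is.null(ds$uns$lr_db)) {
      abort("CCC dataset must carry planted truth and an LR database",
            class = "scbench_validation_error")
    }
  } else {
    rk <- ds$uns$ccc_ranked
    if (is.null(rk) || !all(c("key", "score") %in% names(rk)) ||
        any(!is.finite(rk$score))) {
      abort("method must write a finite ranked key/score table",
            class = "scbench_validation_error")
    }
  }
  invisible(ds)
}

ccc_dataset_fn <- function(test_mode, seed) {
  cfg <- synthetic_config(
    n_cells = if (test_mode) 400 else 1500,
    n_genes = if (test_mode) 200 else 400,
    n_types = 5,
    seed = seed)
  ds <- make_celltype_counts(cfg)
  lr_db <- make_lr_database(ds$gene_meta$gene_id, n_pairs = 50,
                            seed = child_seed(seed, 2))
  planted <- make_ccc_truth(ds, lr_db, n_true_pairs = 10, effect_fold = 20,
                            seed = child_seed(seed, 3))
  ensure_log10k(planted$ds)
}

#' The cell-cell communication subtasks
#'
#' Magnitude and specificity scorers crossed with mean/max aggregation
#' (four methods), oracle-ranking and random-ranking controls, AUPRC and
#' top-5% odds-ratio metrics — one task spec per truth level
#' (source-target or ligand-target).
#'
#' @param level subtask truth level.
#' @return a `task_spec`.
#' @export
task_ccc <- function(level = c("source_target", "ligand_target")) {
  level <- match.arg(level)
  tname <- paste0("ccc_", level)
  spec_scorer <- function(ds) ccc_score_specificity(ds, n_perm = 100)
  task <- task_spec(tname, api_check = ccc_api_check) %>%
    register(dataset_def("planted_lr", ccc_dataset_fn, tname)) %>%
    register(method_def("oracle_ranking",
                        function(ds) ccc_control_oracle(ds, level), tname,
                        role = "positive_control")) %>%
    register(method_def("random_ranking",
                        function(ds) ccc_control_random(ds, level), tname,
                        role = "negative_control")) %>%
    register(method_def("magnitude_mean",
                        ccc_make_method(ccc_score_magnitude, "mean", level),
                        tname)) %>%
    register(method_def("magnitude_max",
                        ccc_make_method(ccc_score_magnitude, "max", level),
                        tname)) %>%
    register(method_def("specificity_mean",
                        ccc_make_method(spec_scorer, "mean", level), tname)) %>%
    register(method_def("specificity_max",
                        ccc_make_method(spec_scorer, "max", level), tname))
  truth_metric <- function(metric_fn, ...) {
    function(ds) metric_fn(ds$uns$ccc_ranked,
                           ccc_truth_keys(ds$truth$ccc, level), ...)
  }
  task %>%
    register(metric_def("auprc", truth_metric(ccc_metric_auprc), tname)) %>%
    register(metric_def("odds_ratio_top5",
                        truth_metric(ccc_metric_odds_ratio), tname))
}
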