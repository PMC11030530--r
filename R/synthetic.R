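#' Synthetic data configuration
#'
#' Parameter bundle for the count generators. Defaults describe the study
#' conditions used throughout the shipped tasks: 2,000 cells, 500 genes,
#' 4 cell types, gamma-Poisson (negative binomial) counts with 10% of
#' genes differentially expressed per type at log-normal fold-change scale
#' 1, gamma-distributed library sizes around 5,000 counts, and
#' multiplicative per-(batch, gene) effects of log-scale sd 1.
#'
#' @param n_cells,n_genes,n_types,n_batches positive integers.
#' @param de_fraction fraction of genes differentially expressed per type.
#' @param de_strength sd of the log-normal DE fold-change factors.
#' @param library_size_mean mean total counts per cell.
#' @param library_size_shape gamma shape of the per-cell library scaling
#'   (larger = less variable).
#' @param batch_strength sd of the log-normal per-(batch, gene) factors.
#' @param nb_size negative binomial size (inverse dispersion) of counts.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 2000, n_genes = 500, n_types = 4,
                             n_batches = 2, de_fraction = 0.1,
                             de_strength = 1, library_size_mean = 5000,
                             library_size_shape = 10, batch_strength = 1,
                             nb_size = 10, seed = 1L) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
              n_batches = n_batches, de_fraction = de_fraction,
              de_strength = de_strength, library_size_mean = library_size_mean,
              library_size_shape = library_size_shape,
              batch_strength = batch_strength, nb_size = nb_size,
              seed = as.integer(seed))
  stopifnot(cfg$n_cells > 0, cfg$n_genes > 0, cfg$n_types > 0,
            cfg$n_batches > 0, cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$de_strength >= 0, cfg$library_size_mean > 0,
            cfg$library_size_shape > 0, cfg$batch_strength >= 0)
  structure(cfg, class = "synthetic_config")
}

#' Generate cell-type-structured counts
#'
#' Draws gamma-Poisson (negative binomial) counts with per-type mean
#' vectors: baseline gene means are log-normal; for each type a
#' `de_fraction` subset of genes has its mean multiplied by log-normal
#' factors of scale `de_strength`; per-cell library scaling is gamma with
#' shape `library_size_shape`. Cell-type labels are written to
#' `cell_meta$label`. Pure function of the config (including its seed).
#'
#' @param cfg a [synthetic_config()].
#' @return a `cbg_dataset` with labels.
#' @export
make_celltype_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_types > cfg$n_cells) {
    abort("n_types must not exceed n_cells", class = "scbench_validation_error")
  }
  withr::with_seed(cfg$seed, {
    base_mean <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    type_means <- matrix(rep(base_mean, each = cfg$n_types),
                         nrow = cfg$n_types)
    n_de <- round(cfg$de_fraction * cfg$n_genes)
    if (cfg$de_strength > 0 && n_de > 0) {
      for (t in seq_len(cfg$n_types)) {
        de_genes <- sample.int(cfg$n_genes, n_de)
        type_means[t, de_genes] <- type_means[t, de_genes] *
          stats::rlnorm(n_de, meanlog = 0, sdlog = cfg$de_strength)
      }
    }
    # row-normalize so library size is controlled by the cell factor alone
    type_means <- type_means / rowSums(type_means)
    labels <- sample(rep_len(seq_len(cfg$n_types), cfg$n_cells))
    lib <- cfg$library_size_mean *
      stats::rgamma(cfg$n_cells, shape = cfg$library_size_shape,
                    rate = cfg$library_size_shape)
    mu <- type_means[labels, , drop = FALSE] * lib
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = cfg$nb_size),
      nrow = cfg$n_cells)
    cbg_dataset(
      counts = counts,
      cell_meta = tibble(cell_id = paste0("cell_", seq_len(cfg$n_cells)),
                         label = paste0("type_", labels)),
      gene_meta = tibble(gene_id = paste0("gene_", seq_len(cfg$n_genes)))
    )
  })
}

#' Add a multiplicative batch effect
#'
#' Assigns cells to batches uniformly at random stratified by cell type,
#' then resamples counts with per-(batch, gene) multiplicative factors
#' drawn log-normal with log-scale sd `batch_strength` (counts stay
#' integer via Poisson resampling at the scaled mean). With
#' `batch_strength = 0` all factors are exactly 1 and counts are
#' unchanged.
#'
#' @param ds a labelled `cbg_dataset`.
#' @param n_batches number of batches (>= 1).
#' @param batch_strength non-negative log-scale sd of the factors.
#' @param seed integer seed.
#' @return the dataset with `cell_meta$batch` set and counts perturbed.
#' @export
add_batch_effect <- function(ds, n_batches, batch_strength, seed = 1L) {
  if (n_batches < 1) {
    abort("n_batches must be >= 1", class = "scbench_validation_error")
  }
  if (is.null(ds$cell_meta[["label"]])) {
    abort("dataset must carry cell-type labels", class = "scbench_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    batch <- integer(n_cells(ds))
    for (lab in unique(ds$cell_meta$label)) {
      idx <- which(ds$cell_meta$label == lab)
      batch[idx] <- sample(rep_len(seq_len(n_batches), length(idx)))
    }
    factors <- matrix(
      if (batch_strength > 0)
        stats::rlnorm(n_batches * n_genes(ds), meanlog = 0, sdlog = batch_strength)
      else 1,
      nrow = n_batches, ncol = n_genes(ds))
    counts <- as_dense(ds$counts)
    if (batch_strength > 0) {
      f_cells <- factors[batch, , drop = FALSE]
      resample <- f_cells != 1
      counts[resample] <- stats::rpois(sum(resample),
                                       counts[resample] * f_cells[resample])
    }
    ds$counts <- pack_matrix(counts)
    ds$cell_meta$batch <- paste0("batch_", batch)
    ds$uns$batch_factors <- factors
    ds
  })
}

#' Mix reference cells into synthetic spatial spots
#'
#' For each spot: true type proportions are Dirichlet(`dirichlet_alpha`),
#' the number of contributing cells is Poisson(`cells_per_spot_mean`)
#' (minimum 1), each cell's type is drawn from the proportions and a
#' reference cell of that type is sampled with replacement; the spot's
#' counts are the sum of the sampled cells' counts. The true proportions
#' are stored row-stochastic under `truth$proportions` (columns named by
#' type) and the reference dataset under `uns$reference`.
#'
#' @param reference a labelled `cbg_dataset` with >= 2 types.
#' @param n_spots number of capture locations.
#' @param cells_per_spot_mean Poisson mean of cells per spot.
#' @param dirichlet_alpha scalar Dirichlet concentration.
#' @param seed integer seed.
#' @return a `cbg_dataset` of spots.
#' @export
make_spatial_mixture <- function(reference, n_spots = 100,
                                 cells_per_spot_mean = 20,
                                 dirichlet_alpha = 1, seed = 1L) {
  if (is.null(reference$cell_meta[["label"]])) {
    abort("reference must carry cell-type labels", class = "scbench_validation_error")
  }
  types <- sort(unique(reference$cell_meta$label))
  if (length(types) < 2) {
    abort("reference needs >= 2 cell types", class = "scbench_validation_error")
  }
  ref_counts <- as_dense(reference$counts)
  idx_by_type <- map(types, function(tt) which(reference$cell_meta$label == tt))
  withr::with_seed(as.integer(seed), {
    props <- matrix(stats::rgamma(n_spots * length(types),
                                  shape = dirichlet_alpha, rate = 1),
                    nrow = n_spots)
    props <- props / rowSums(props)
    colnames(props) <- types
    spot_counts <- matrix(0, nrow = n_spots, ncol = ncol(ref_counts))
    for (s in seq_len(n_spots)) {
      nc <- max(1L, stats::rpois(1, cells_per_spot_mean))
      cell_types <- sample.int(length(types), nc, replace = TRUE,
                               prob = props[s, ])
      cells <- vapply(cell_types, function(ti) {
        pool <- idx_by_type[[ti]]
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      spot_counts[s, ] <- colSums(ref_counts[cells, , drop = FALSE])
    }
    cbg_dataset(
      counts = spot_counts,
      cell_meta = tibble(cell_id = paste0("spot_", seq_len(n_spots))),
      gene_meta = reference$gene_meta,
      truth = list(proportions = props, type_order = types),
      uns = list(reference = reference)
    )
  })
}

#' Generate paired multimodal views of the same cells
#'
#' A shared latent matrix Z (standard normal, `n_cells` x `d_latent`) is
#' mapped into two modality views through random linear maps plus Gaussian
#' noise. The first `n_shared_features` columns of both views use the SAME
#' map (the shared feature block methods may exploit). Row i of both views
#' is the same cell; the ground-truth pairing (identity permutation) is
#' stored under `truth$pairing` of the returned object.
#'
#' The views are real-valued, so they are returned as a `modality_pair`
#' object (fields `X1`, `X2`, `n_shared_features`, `truth`, `embeddings`)
#' rather than as count datasets.
#'
#' @param n_cells,d_latent,d1,d2 dimensions; `d1, d2 >= d_latent`.
#' @param n_shared_features size of the shared block
#'   (`<= min(d1, d2)`).
#' @param noise_sd Gaussian noise sd added to both views.
#' @param seed integer seed.
#' @return a `modality_pair`.
#' @export
make_paired_modalities <- function(n_cells = 500, d_latent = 10, d1 = 50,
                                   d2 = 40, n_shared_features = 20,
                                   noise_sd = 0.1, seed = 1L) {
  if (d1 < d_latent || d2 < d_latent) {
    abort("d1 and d2 must be >= d_latent", class = "scbench_validation_error")
  }
  if (n_shared_features > min(d1, d2)) {
    abort("n_shared_features must be <= min(d1, d2)",
          class = "scbench_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    Z <- matrix(stats::rnorm(n_cells * d_latent), nrow = n_cells)
    W_shared <- matrix(stats::rnorm(d_latent * n_shared_features), nrow = d_latent)
    W1_rest <- matrix(stats::rnorm(d_latent * (d1 - n_shared_features)), nrow = d_latent)
    W2_rest <- matrix(stats::rnorm(d_latent * (d2 - n_shared_features)), nrow = d_latent)
    X1 <- Z %*% cbind(W_shared, W1_rest) +
      noise_sd * matrix(stats::rnorm(n_cells * d1), nrow = n_cells)
    X2 <- Z %*% cbind(W_shared, W2_rest) +
      noise_sd * matrix(stats::rnorm(n_cells * d2), nrow = n_cells)
    structure(
      list(X1 = X1, X2 = X2, n_shared_features = n_shared_features,
           cell_ids = paste0("cell_", seq_len(n_cells)),
           embeddings = list(),
           truth = list(pairing = seq_len(n_cells))),
      class = "modality_pair")
  })
}

#' @export
print.modality_pair <- function(x, ...) {
  cat(sprintf("<modality_pair> %d cells; views %d + %d features (%d shared)\n",
              nrow(x$X1), ncol(x$X1), ncol(x$X2), x$n_shared_features))
  invisible(x)
}

#' Synthetic ligand-receptor catalogue
#'
#' Draws `n_pairs` disjoint (ligand, receptor) gene pairs from the
#' dataset's gene panel; no external resource is used.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @return tibble with columns `ligand`, `receptor`.
#' @export
make_lr_database <- function(gene_ids, n_pairs = 50, seed = 1L) {
  if (length(gene_ids) < 2 * n_pairs) {
    abort("need at least 2 * n_pairs genes", class = "scbench_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    genes <- sample(gene_ids, 2 * n_pairs)
    tibble(ligand = genes[seq_len(n_pairs)],
           receptor = genes[n_pairs + seq_len(n_pairs)])
  })
}

#' Plant ligand-receptor communication ground truth
#'
#' Selects `n_true_pairs` (source type, target type, LR pair) triples
#' uniformly without replacement from the full combination space, then
#' scales the ligand gene's counts in source-type cells and the receptor
#' gene's counts in target-type cells by `effect_fold` (integer counts
#' preserved by Poisson resampling at the scaled mean; `effect_fold = 1`
#' leaves counts untouched). The truth records the positive
#' (source, target) and (ligand, target) sets.
#'
#' @param ds a labelled `cbg_dataset` with >= 2 types.
#' @param lr_db tibble from [make_lr_database()].
#' @param n_true_pairs number of planted triples.
#' @param effect_fold multiplicative up-regulation of planted genes.
#' @param seed integer seed.
#' @return list with elements `ds` (perturbed dataset, truth attached) and
#'   `truth` (list: `triples`, `positive_st`, `positive_lt`).
#' @export
make_ccc_truth <- function(ds, lr_db, n_true_pairs = 10, effect_fold = 20,
                           seed = 1L) {
  labels <- ds$cell_meta[["label"]]
  if (is.null(labels) || length(unique(labels)) < 2) {
    abort("dataset needs >= 2 cell types", class = "scbench_validation_error")
  }
  if (nrow(lr_db) == 0) {
    abort("lr_db is empty", class = "scbench_validation_error")
  }
  missing_genes <- setdiff(c(lr_db$ligand, lr_db$receptor), ds$gene_meta$gene_id)
  if (length(missing_genes)) {
    abort(sprintf("LR genes absent from dataset: %s",
                  paste(utils::head(missing_genes, 5), collapse = ", ")),
          class = "scbench_validation_error")
  }
  types <- sort(unique(labels))
  combos <- expand.grid(source = types, target = types,
                        pair = seq_len(nrow(lr_db)),
                        stringsAsFactors = FALSE)
  if (n_true_pairs > nrow(combos)) {
    abort("n_true_pairs exceeds the number of available combinations",
          class = "scbench_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    chosen <- combos[sample.int(nrow(combos), n_true_pairs), , drop = FALSE]
    counts <- as_dense(ds$counts)
    gene_index <- stats::setNames(seq_len(n_genes(ds)), ds$gene_meta$gene_id)
    if (effect_fold != 1) {
      for (r in seq_len(nrow(chosen))) {
        lg <- gene_index[[lr_db$ligand[chosen$pair[r]]]]
        rg <- gene_index[[lr_db$receptor[chosen$pair[r]]]]
        src <- labels == chosen$source[r]
        tgt <- labels == chosen$target[r]
        counts[src, lg] <- stats::rpois(sum(src), counts[src, lg] * effect_fold)
        counts[tgt, rg] <- stats::rpois(sum(tgt), counts[tgt, rg] * effect_fold)
      }
    }
    triples <- tibble(source = chosen$source, target = chosen$target,
                      ligand = lr_db$ligand[chosen$pair],
                      receptor = lr_db$receptor[chosen$pair])
    truth <- list(
      triples = triples,
      positive_st = distinct(triples[, c("source", "target")]),
      positive_lt = distinct(triples[, c("ligand", "target")])
    )
    ds$counts <- pack_matrix(counts)
    ds$truth$ccc <- truth
    ds$uns$lr_db <- lr_db
    list(ds = ds, truth = truth)
  })
}
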