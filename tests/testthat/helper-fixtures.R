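# Small fixtures shared across test files; everything is generated in code.

tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_cells = 120, n_genes = 60, n_types = 3, seed = seed)
  defaults[names(args)] <- args
  do.call(synthetic_config, defaults)
}

tiny_dataset <- function(seed = 1L, ...) {
  make_celltype_counts(tiny_config(seed = seed, ...))
}

random_counts <- function(n_cells, n_genes, seed = 1L, lambda = 3) {
  withr::with_seed(seed, {
    matrix(stats::rpois(n_cells * n_genes, lambda), nrow = n_cells)
  })
}

# A hand-built score table: one dataset, one maximize metric, two controls
# (raw 0.2 and 0.9) plus one ordinary method.
toy_score_table <- function(method_raw = 0.55) {
  new_score_table(
    raw = tibble::tibble(
      dataset = "d1",
      method = c("pos", "neg", "m"),
      metric = "acc",
      value = c(0.9, 0.2, method_raw)),
    roles = tibble::tibble(
      method = c("pos", "neg", "m"),
      role = c("positive_control", "negative_control", "method")),
    orientations = tibble::tibble(metric = "acc", orientation = "maximize"),
    task = "toy")
}
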