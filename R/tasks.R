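#' All shipped tasks
#'
#' Builds the full roster of task specifications: label projection,
#' denoising, dimensionality reduction, the three batch integration
#' subtasks, spatial decomposition, matching modalities, and the two
#' cell-cell communication subtasks.
#'
#' @return named list of `task_spec`s.
#' @export
all_tasks <- function() {
  specs <- list(
    task_label_projection(),
    task_denoising(),
    task_dimred(),
    task_batch_integration("matrix"),
    task_batch_integration("embedding"),
    task_batch_integration("graph"),
    task_spatial_decomposition(),
    task_matching_modalities(),
    task_ccc("source_target"),
    task_ccc("ligand_target")
  )
  stats::setNames(specs, map_chr(specs, "name"))
}

#' Look up a shipped task by name
#'
#' @param name task name (see [all_tasks()]).
#' @return a `task_spec`.
#' @export
get_task <- function(name) {
  tasks <- all_tasks()
  if (!name %in% names(tasks)) {
    abort(sprintf("unknown task '%s'; available: %s", name,
                  paste(names(tasks), collapse = ", ")),
          class = "scbench_configuration_error")
  }
  tasks[[name]]
}

#' Summary of shipped tasks and their maturity
#'
#' @return tibble with columns `task`, `maturity`, `n_datasets`,
#'   `n_methods`, `n_metrics`.
#' @export
list_tasks <- function() {
  tasks <- all_tasks()
  tibble(
    task = names(tasks),
    maturity = map_chr(tasks, classify_maturity),
    n_datasets = vapply(tasks, function(t) length(t$datasets), integer(1)),
    n_methods = vapply(tasks, function(t) length(t$methods), integer(1)),
    n_metrics = vapply(tasks, function(t) length(t$metrics), integer(1))
  )
}
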