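#' Component definitions
#'
#' A task is assembled from three component kinds, each a single function:
#' datasets build a `cbg_dataset` with ground truth from `(test_mode, seed)`;
#' methods take the dataset and return it with output slots filled; metrics
#' take the method output and return one real number. Methods carry a role:
#' ordinary `"method"`, or one of the two control roles
#' (`"positive_control"`, `"negative_control"`) used to anchor score
#' normalization at 1 and 0.
#'
#' @param name component name, unique within its kind inside a task.
#' @param fn the component function (see Details above).
#' @param task name of the task the component belongs to.
#' @param role method role.
#' @param orientation whether larger (`"maximize"`) or smaller
#'   (`"minimize"`) raw metric values are better.
#' @return a `dataset_def`, `method_def` or `metric_def` object.
#' @name components
NULL

#' @rdname components
#' @export
dataset_def <- function(name, fn, task) {
  structure(list(name = name, fn = fn, task = task),
            class = c("dataset_def", "component_def"))
}

#' @rdname components
#' @export
method_def <- function(name, fn, task,
                       role = c("method", "positive_control", "negative_control")) {
  role <- match.arg(role)
  structure(list(name = name, fn = fn, task = task, role = role),
            class = c("method_def", "component_def"))
}

#' @rdname components
#' @export
metric_def <- function(name, fn, task, orientation = c("maximize", "minimize")) {
  orientation <- match.arg(orientation)
  structure(list(name = name, fn = fn, task = task, orientation = orientation),
            class = c("metric_def", "component_def"))
}

#' Create an empty task specification
#'
#' @param name task name.
#' @param api_check optional `function(ds, stage)` validating dataset slots
#'   before methods run (`stage = "dataset"`) and after each method
#'   (`stage = "method"`); should abort on violation.
#' @return a `task_spec`.
#' @export
task_spec <- function(name, api_check = NULL) {
  structure(list(name = name, datasets = list(), methods = list(),
                 metrics = list(), api_check = api_check),
            class = "task_spec")
}

component_kind <- function(component) {
  if (inherits(component, "dataset_def")) "datasets"
  else if (inherits(component, "method_def")) "methods"
  else if (inherits(component, "metric_def")) "metrics"
  else abort("not a component definition", class = "scbench_registration_error")
}

#' Register a component into a task
#'
#' Components are appended in registration order; duplicate names within a
#' kind and mismatched task tags are registration errors.
#'
#' @param task a `task_spec`.
#' @param component a `dataset_def`, `method_def` or `metric_def`.
#' @return the updated `task_spec`.
#' @export
register <- function(task, component) {
  stopifnot(inherits(task, "task_spec"))
  kind <- component_kind(component)
  if (!identical(component$task, task$name)) {
    abort(sprintf("component '%s' is tagged for task '%s', not '%s'",
                  component$name, component$task, task$name),
          class = "scbench_registration_error")
  }
  existing <- map_chr(task[[kind]], "name")
  if (component$name %in% existing) {
    abort(sprintf("%s '%s' is already registered in task '%s'",
                  sub("s$", "", kind), component$name, task$name),
          class = "scbench_registration_error")
  }
  task[[kind]] <- c(task[[kind]], list(component))
  task
}

#' Classify task maturity
#'
#' A task is `"full"` with at least two datasets, six methods and one
#' metric; a `"stub"` with at least one dataset, three methods and one
#' metric; anything less is `"under_discussion"`. Control-role methods
#' count toward the method tally.
#'
#' @param task a `task_spec`.
#' @return one of `"under_discussion"`, `"stub"`, `"full"`.
#' @export
classify_maturity <- function(task) {
  nd <- length(task$datasets)
  nm <- length(task$methods)
  nx <- length(task$metrics)
  if (nd >= 2 && nm >= 6 && nx >= 1) "full"
  else if (nd >= 1 && nm >= 3 && nx >= 1) "stub"
  else "under_discussion"
}

# Runnable completeness: >=1 dataset, >=1 metric, and both control roles
# ("at least one dataset, one metric, and two baseline methods").
check_complete <- function(task) {
  roles <- map_chr(task$methods, "role")
  if (length(task$datasets) < 1 || length(task$metrics) < 1 ||
      !all(c("positive_control", "negative_control") %in% roles)) {
    abort(sprintf(
      "task '%s' is incomplete: needs >=1 dataset, >=1 metric and both control roles",
      task$name), class = "scbench_configuration_error")
  }
  invisible(task)
}

#' @export
print.task_spec <- function(x, ...) {
  roles <- map_chr(x$methods, "role")
  cat(sprintf("<task_spec> %s [%s]\n", x$name, classify_maturity(x)))
  cat(sprintf("  datasets: %s\n", paste(map_chr(x$datasets, "name"), collapse = ", ")))
  cat(sprintf("  methods:  %s\n",
              paste(sprintf("%s(%s)", map_chr(x$methods, "name"),
                            substr(roles, 1, 3)), collapse = ", ")))
  cat(sprintf("  metrics:  %s\n", paste(map_chr(x$metrics, "name"), collapse = ", ")))
  invisible(x)
}
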