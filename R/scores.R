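#' Score table
#'
#' The result container of a benchmark run. `raw` holds one row per
#' (dataset, method, metric) triple with the raw metric value (`NA` when
#' the method failed); `normalized`, `overall` and `rank` are filled by
#' [normalize_scores()] and [overall_score()]. Component metadata (method
#' roles, metric orientations) travels with the table so it can be
#' normalized and serialized without the originating `task_spec`.
#'
#' @param raw tibble with columns `dataset`, `method`, `metric`, `value`.
#' @param roles tibble with columns `method`, `role`.
#' @param orientations tibble with columns `metric`, `orientation`.
#' @param task task name.
#' @param resources optional tibble with columns `dataset`, `method`,
#'   `runtime_s`, `peak_mem_bytes`.
#' @param seed integer seed the run used.
#' @return a `score_table`.
#' @export
new_score_table <- function(raw, roles, orientations, task = "task",
                            resources = NULL, seed = NA_integer_) {
  raw <- as_tibble(raw)
  stopifnot(all(c("dataset", "method", "metric", "value") %in% names(raw)))
  structure(
    list(task = task, raw = raw, normalized = NULL, overall = NULL,
         roles = as_tibble(roles), orientations = as_tibble(orientations),
         resources = resources %||%
           tibble(dataset = character(), method = character(),
                  runtime_s = numeric(), peak_mem_bytes = numeric()),
         seed = seed),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> task '%s', %d datasets x %d methods x %d metrics\n",
              x$task, dplyr::n_distinct(x$raw$dataset),
              dplyr::n_distinct(x$raw$method), dplyr::n_distinct(x$raw$metric)))
  if (!is.null(x$overall)) {
    print(x$overall, n = 20)
  } else {
    print(x$raw, n = 10)
  }
  invisible(x)
}

# Oriented copy of raw values: larger is always better.
orient_values <- function(raw, orientations) {
  raw %>%
    left_join(orientations, by = "metric") %>%
    mutate(oriented = ifelse(.data$orientation == "minimize",
                             -.data$value, .data$value))
}

#' Baseline-anchored score normalization
#'
#' Per (dataset, metric), raw scores are oriented so that larger is better
#' (minimize metrics are negated), then linearly rescaled so the best
#' control-role method maps to 1 and the worst to 0:
#' `(x - worst) / (best - worst)` with best/worst the max/min oriented
#' score over positive/negative controls. Values are not clipped, so
#' methods can score above 1 or arbitrarily below 0. Degenerate anchors
#' (best == worst) yield `NA` for that (dataset, metric) with a warning.
#'
#' @param table a `score_table` with `raw` populated.
#' @param task optional `task_spec`; roles/orientations embedded in the
#'   table are used when omitted.
#' @return the `score_table` with `normalized` filled.
#' @export
normalize_scores <- function(table, task = NULL) {
  stopifnot(inherits(table, "score_table"))
  roles <- table$roles
  controls <- roles$method[roles$role %in% c("positive_control", "negative_control")]
  if (length(controls) < 2) {
    abort("normalization needs both control roles in the table",
          class = "scbench_configuration_error")
  }
  oriented <- orient_values(table$raw, table$orientations)
  anchors <- oriented %>%
    filter(.data$method %in% controls, !is.na(.data$oriented)) %>%
    group_by(.data$dataset, .data$metric) %>%
    summarise(best = max(.data$oriented), worst = min(.data$oriented),
              .groups = "drop")
  degen <- anchors %>% filter(.data$best == .data$worst)
  if (nrow(degen) > 0) {
    warn(sprintf("degenerate baseline anchors (best == worst) for: %s",
                 paste(paste(degen$dataset, degen$metric, sep = "/"),
                       collapse = ", ")))
  }
  table$normalized <- oriented %>%
    left_join(anchors, by = c("dataset", "metric")) %>%
    mutate(value = ifelse(
      is.na(.data$oriented) | is.na(.data$best) | .data$best == .data$worst,
      NA_real_,
      (.data$oriented - .data$worst) / (.data$best - .data$worst))) %>%
    select("dataset", "method", "metric", "value")
  table
}

#' Overall scores and per-dataset ranks
#'
#' The overall score of a method on a dataset is the arithmetic mean of
#' its non-missing normalized metric scores there. Ranks are assigned per
#' dataset in descending overall score with competition ranking (ties
#' share the smaller rank, the next rank is skipped); methods whose
#' normalized scores are all missing rank last.
#'
#' @param table a `score_table` with `normalized` populated.
#' @return the `score_table` with `overall` filled (columns `dataset`,
#'   `method`, `overall`, `rank`).
#' @export
overall_score <- function(table) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(table$normalized)) {
    abort("run normalize_scores() first", class = "scbench_configuration_error")
  }
  table$overall <- table$normalized %>%
    group_by(.data$dataset, .data$method) %>%
    summarise(overall = if (all(is.na(.data$value))) NA_real_
              else mean(.data$value, na.rm = TRUE),
              .groups = "drop") %>%
    group_by(.data$dataset) %>%
    mutate(rank = competition_rank(.data$overall)) %>%
    ungroup()
  table
}

# Competition ranking (1,2,2,4) on descending score; NA ranks after all
# non-NA values, tied NAs share a rank.
competition_rank <- function(score) {
  key <- ifelse(is.na(score), -Inf, score)
  n_better <- vapply(key, function(s) sum(key > s), integer(1))
  as.integer(n_better + 1L)
}

#' Collate overall scores across subtasks
#'
#' Cross-subtask score of a method = unweighted mean of its per-subtask
#' overall scores (each subtask's overall first averaged over that
#' subtask's datasets), taken over the subtasks where the method ran.
#' Methods absent from some subtasks are flagged as partial coverage.
#'
#' @param tables list of `score_table`s with `overall` populated.
#' @param method_names optional character vector restricting/ordering the
#'   output methods.
#' @return tibble with columns `method`, `score`, `n_subtasks`, `partial`.
#' @export
collate_subtasks <- function(tables, method_names = NULL) {
  per <- map(tables, function(tb) {
    stopifnot(inherits(tb, "score_table"))
    if (is.null(tb$overall)) abort("tables need overall_score() applied")
    tb$overall %>%
      group_by(.data$method) %>%
      summarise(subtask_score = mean(.data$overall, na.rm = FALSE),
                .groups = "drop") %>%
      mutate(task = tb$task)
  })
  out <- bind_rows(per) %>%
    filter(!is.na(.data$subtask_score)) %>%
    group_by(.data$method) %>%
    summarise(score = mean(.data$subtask_score),
              n_subtasks = dplyr::n(), .groups = "drop") %>%
    mutate(partial = .data$n_subtasks < length(tables)) %>%
    arrange(desc(.data$score))
  if (!is.null(method_names)) {
    out <- out %>% filter(.data$method %in% method_names)
  }
  out
}

RESULTS_SCHEMA_VERSION <- "1.0"

#' Export / import benchmark results as JSON
#'
#' Writes the score table together with component metadata, seed and a
#' timestamp to a JSON document (schema shipped under
#' `inst/schema/results-schema.json`). Missing values are serialized as
#' `null` and restored as `NA`. `import_results()` reverses the export.
#'
#' @param table a `score_table`.
#' @param task optional `task_spec` (names/roles recorded from the table
#'   when omitted).
#' @param path output / input file path.
#' @return `export_results()`: `path`, invisibly. `import_results()`: a
#'   `score_table`.
#' @export
export_results <- function(table, task = NULL, path) {
  stopifnot(inherits(table, "score_table"))
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    abort(sprintf("cannot write '%s': directory '%s' does not exist", path, parent),
          class = "scbench_io_error")
  }
  doc <- list(
    schema_version = RESULTS_SCHEMA_VERSION,
    task = table$task,
    seed = table$seed,
    timestamp = timestamp_utc(),
    components = list(
      datasets = unique(table$raw$dataset),
      methods = table$roles,
      metrics = table$orientations
    ),
    raw = table$raw,
    normalized = table$normalized,
    overall = table$overall,
    resources = table$resources
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname export_results
#' @export
import_results <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "scbench_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_results_json(doc)
  df_or_null <- function(x, cols) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(NULL)
    x <- as_tibble(x)
    for (cn in cols) if (!cn %in% names(x)) x[[cn]] <- NA_real_
    x
  }
  tb <- new_score_table(
    raw = as_tibble(doc$raw) %>%
      mutate(value = as.numeric(.data$value)),
    roles = as_tibble(doc$components$methods),
    orientations = as_tibble(doc$components$metrics),
    task = doc$task,
    resources = df_or_null(doc$resources,
                           c("dataset", "method", "runtime_s", "peak_mem_bytes")),
    seed = doc$seed %||% NA_integer_
  )
  norm <- df_or_null(doc$normalized, "value")
  if (!is.null(norm)) tb$normalized <- norm %>% mutate(value = as.numeric(.data$value))
  ov <- df_or_null(doc$overall, "overall")
  if (!is.null(ov)) {
    tb$overall <- ov %>% mutate(overall = as.numeric(.data$overall),
                                rank = as.integer(.data$rank))
  }
  tb
}

#' Structural validation of a results JSON document
#'
#' Checks the document against the shipped schema's required fields and
#' basic types; aborts with a descriptive error on violation.
#'
#' @param doc a list parsed from a results JSON file.
#' @return `TRUE`, invisibly.
#' @export
validate_results_json <- function(doc) {
  need <- c("schema_version", "task", "components", "raw")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    abort(sprintf("results document missing fields: %s",
                  paste(missing, collapse = ", ")),
          class = "scbench_validation_error")
  }
  if (!is.character(doc$task) && !is.null(doc$task)) {
    abort("'task' must be a string", class = "scbench_validation_error")
  }
  raw <- as_tibble(doc$raw)
  need_cols <- c("dataset", "method", "metric", "value")
  if (!all(need_cols %in% names(raw))) {
    abort("'raw' must have dataset/method/metric/value columns",
          class = "scbench_validation_error")
  }
  comp <- doc$components
  if (!all(c("methods", "metrics") %in% names(comp))) {
    abort("'components' must list methods and metrics",
          class = "scbench_validation_error")
  }
  invisible(TRUE)
}
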