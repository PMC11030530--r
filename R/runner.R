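#' Run a task's full benchmark
#'
#' Evaluates every registered method on every dataset with every metric.
#' A method failure on a dataset is isolated: its metric values are
#' recorded as missing (with a logged diagnostic) and the run continues.
#' Wall-clock runtime and approximate peak memory are recorded per
#' (dataset, method). With a fixed seed the run is reproducible
#' end-to-end for deterministic components: every method call receives a
#' child seed derived from `seed` and the method's position.
#'
#' @param task a complete `task_spec` (>=1 dataset, >=1 metric, both
#'   control roles present).
#' @param test_mode logical; passed to dataset functions, which must
#'   return a reduced dataset (<= 500 cells) when `TRUE`.
#' @param seed integer seed for the whole run.
#' @param quiet suppress per-component log lines.
#' @return a `score_table` with `raw` and `resources` populated.
#' @export
run_benchmark <- function(task, test_mode = TRUE, seed = 1L, quiet = TRUE) {
  check_complete(task)
  metric_names <- map_chr(task$metrics, "name")
  rows <- list()
  res_rows <- list()
  for (d in task$datasets) {
    ds <- d$fn(test_mode = test_mode, seed = seed)
    if (!is.null(task$api_check)) task$api_check(ds, stage = "dataset")
    for (mi in seq_along(task$methods)) {
      m <- task$methods[[mi]]
      gc(reset = TRUE, verbose = FALSE)
      t0 <- proc.time()[["elapsed"]]
      # method calls use a seed stream disjoint from the small stream
      # indices dataset generators draw their child seeds from
      out <- tryCatch(
        withr::with_seed(child_seed(seed, 500L + mi), m$fn(ds)),
        error = function(e) {
          log_msg("WARN", sprintf("method '%s' failed on dataset '%s': %s",
                                  m$name, d$name, conditionMessage(e)))
          NULL
        }
      )
      runtime <- proc.time()[["elapsed"]] - t0
      gcinfo <- gc(verbose = FALSE)
      peak_bytes <- sum(gcinfo[, "max used"] * c(56, 8))
      res_rows[[length(res_rows) + 1L]] <- tibble(
        dataset = d$name, method = m$name,
        runtime_s = runtime, peak_mem_bytes = peak_bytes)
      if (!is.null(out) && !is.null(task$api_check)) {
        out <- tryCatch({
          task$api_check(out, stage = "method")
          out
        }, error = function(e) {
          log_msg("WARN", sprintf("method '%s' output failed api check on '%s': %s",
                                  m$name, d$name, conditionMessage(e)))
          NULL
        })
      }
      for (x in task$metrics) {
        val <- if (is.null(out)) NA_real_ else tryCatch(
          as.numeric(x$fn(out)),
          error = function(e) {
            log_msg("WARN", sprintf("metric '%s' failed for method '%s' on '%s': %s",
                                    x$name, m$name, d$name, conditionMessage(e)))
            NA_real_
          }
        )
        rows[[length(rows) + 1L]] <- tibble(
          dataset = d$name, method = m$name, metric = x$name, value = val)
      }
      if (!quiet) {
        log_msg("INFO", sprintf("%s / %s: %.2fs", d$name, m$name, runtime))
      }
    }
  }
  new_score_table(
    raw = bind_rows(rows),
    roles = tibble(method = map_chr(task$methods, "name"),
                   role = map_chr(task$methods, "role")),
    orientations = tibble(metric = metric_names,
                          orientation = map_chr(task$metrics, "orientation")),
    task = task$name,
    resources = bind_rows(res_rows),
    seed = as.integer(seed)
  )
}

#' Run, normalize and rank in one call
#'
#' Convenience wrapper chaining [run_benchmark()], [normalize_scores()]
#' and [overall_score()].
#'
#' @inheritParams run_benchmark
#' @return a `score_table` with all slots populated.
#' @export
benchmark_task <- function(task, test_mode = TRUE, seed = 1L, quiet = TRUE) {
  run_benchmark(task, test_mode = test_mode, seed = seed, quiet = quiet) %>%
    normalize_scores(task) %>%
    overall_score()
}
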