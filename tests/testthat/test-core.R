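dummy_task <- function(n_datasets = 1, n_methods = 0, n_metrics = 1,
                       with_controls = TRUE, failing_method = FALSE) {
  t <- task_spec("dummy")
  for (i in seq_len(n_datasets)) {
    t <- register(t, dataset_def(
      paste0("d", i),
      function(test_mode, seed) {
        withr::with_seed(seed, cbg_dataset(matrix(rpois(20, 5), 4)))
      }, "dummy"))
  }
  if (with_controls) {
    t <- t %>%
      register(method_def("pos", function(ds) { ds$uns$y <- 1; ds }, "dummy",
                          role = "positive_control")) %>%
      register(method_def("neg", function(ds) { ds$uns$y <- 0; ds }, "dummy",
                          role = "negative_control"))
  }
  for (i in seq_len(n_methods)) {
    val <- 0.2 + 0.1 * i
    t <- register(t, method_def(
      paste0("m", i),
      local({
        v <- val
        function(ds) { ds$uns$y <- v; ds }
      }), "dummy"))
  }
  if (failing_method) {
    t <- register(t, method_def("boom", function(ds) stop("kaput"), "dummy"))
  }
  for (i in seq_len(n_metrics)) {
    t <- register(t, metric_def(
      paste0("x", i),
      local({
        off <- i / 10
        function(ds) ds$uns$y + off
      }), "dummy"))
  }
  t
}

test_that("registration preserves order and rejects duplicates and wrong tags", {
  t <- task_spec("t")
  for (nm in c("a", "b", "c")) {
    t <- register(t, method_def(nm, identity, "t"))
  }
  expect_equal(vapply(t$methods, `[[`, "", "name"), c("a", "b", "c"))
  expect_error(register(t, method_def("a", identity, "t")),
               class = "scbench_registration_error")
  expect_error(register(t, metric_def("acc", identity, "other")),
               class = "scbench_registration_error")
  t <- register(t, metric_def("acc", identity, "t"))
  expect_error(register(t, metric_def("acc", identity, "t")),
               class = "scbench_registration_error")
})

test_that("maturity thresholds match the printed component counts exactly", {
  expect_equal(classify_maturity(dummy_task(1, 1, 1)), "stub")       # 3 methods
  expect_equal(classify_maturity(dummy_task(2, 4, 1)), "full")       # 6 methods
  expect_equal(classify_maturity(dummy_task(1, 0, 1)), "under_discussion")
  expect_equal(classify_maturity(dummy_task(2, 3, 1)), "stub")       # 5 methods
  expect_equal(classify_maturity(dummy_task(1, 4, 1)), "stub")       # 1 dataset
  expect_equal(classify_maturity(dummy_task(2, 4, 0)), "under_discussion")
})

test_that("the runner produces the full grid and isolates failures", {
  t <- dummy_task(n_methods = 0, n_metrics = 2)
  tb <- run_benchmark(t, seed = 1)
  expect_equal(nrow(tb$raw), 1 * 2 * 2)
  expect_true(all(!is.na(tb$raw$value)))
  expect_equal(nrow(tb$resources), 2)

  t2 <- dummy_task(n_methods = 1, n_metrics = 2, failing_method = TRUE)
  tb2 <- suppressMessages(run_benchmark(t2, seed = 1))
  boom <- tb2$raw %>% dplyr::filter(method == "boom")
  expect_equal(nrow(boom), 2)
  expect_true(all(is.na(boom$value)))
  ok <- tb2$raw %>% dplyr::filter(method != "boom")
  expect_true(all(!is.na(ok$value)))
})

test_that("incomplete tasks are rejected before execution", {
  expect_error(run_benchmark(dummy_task(with_controls = FALSE, n_methods = 2)),
               class = "scbench_configuration_error")
})

test_that("fixed seeds reproduce the raw table", {
  t <- dummy_task(n_methods = 2, n_metrics = 2)
  tb1 <- run_benchmark(t, seed = 11)
  tb2 <- run_benchmark(t, seed = 11)
  expect_equal(tb1$raw, tb2$raw)
})

test_that("normalization anchors controls at 1 and 0 and allows sub-zero scores", {
  tb <- toy_score_table(method_raw = 0.55) %>% normalize_scores()
  norm <- tb$normalized
  expect_equal(norm$value[norm$method == "pos"], 1)
  expect_equal(norm$value[norm$method == "neg"], 0)
  expect_equal(norm$value[norm$method == "m"], 0.5)

  tb0 <- toy_score_table(method_raw = 0) %>% normalize_scores()
  expect_equal(tb0$normalized$value[tb0$normalized$method == "m"],
               (0 - 0.2) / 0.7, tolerance = 1e-12)
  expect_lt(tb0$normalized$value[tb0$normalized$method == "m"], 0)
})

test_that("degenerate anchors yield missing normalized values with a warning", {
  tb <- toy_score_table()
  tb$raw$value[tb$raw$method %in% c("pos", "neg")] <- 0.4
  expect_warning(tb <- normalize_scores(tb), "degenerate")
  expect_true(all(is.na(tb$normalized$value)))
})

test_that("normalization is equivariant under increasing affine transforms", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      raw <- tibble::tibble(
        dataset = "d", metric = "m",
        method = c("pos", "neg", "a", "b"),
        value = rnorm(4))
      roles <- tibble::tibble(
        method = c("pos", "neg", "a", "b"),
        role = c("positive_control", "negative_control", "method", "method"))
      orient <- tibble::tibble(metric = "m",
                               orientation = sample(c("maximize", "minimize"), 1))
      t1 <- new_score_table(raw, roles, orient) %>% normalize_scores()
      a <- runif(1, 0.1, 5); b <- rnorm(1)
      raw2 <- raw
      raw2$value <- a * raw$value + b
      t2 <- new_score_table(raw2, roles, orient) %>% normalize_scores()
      expect_equal(t1$normalized$value, t2$normalized$value, tolerance = 1e-9)

      # orientation flip: negate raws, flip the flag
      raw3 <- raw
      raw3$value <- -raw$value
      orient3 <- orient
      orient3$orientation <- setdiff(c("maximize", "minimize"),
                                     orient$orientation)
      t3 <- new_score_table(raw3, roles, orient3) %>% normalize_scores()
      expect_equal(t1$normalized$value, t3$normalized$value, tolerance = 1e-9)
    }
  })
})

test_that("overall scores average non-missing metrics and ranks share ties", {
  raw <- tidyr::expand_grid(dataset = "d",
                            method = c("pos", "neg", "a", "b"),
                            metric = c("m1", "m2")) %>%
    dplyr::mutate(value = c(1, 1, 0, 0, 1, 0.5, 1, 0.5))
  roles <- tibble::tibble(
    method = c("pos", "neg", "a", "b"),
    role = c("positive_control", "negative_control", "method", "method"))
  orient <- tibble::tibble(metric = c("m1", "m2"),
                           orientation = "maximize")
  tb <- new_score_table(raw, roles, orient) %>%
    normalize_scores() %>% overall_score()
  ov <- tb$overall
  expect_equal(ov$overall[ov$method == "a"], 0.75)
  expect_equal(ov$overall[ov$method == "b"], 0.75)
  # competition ranking: pos=1, a=b tie at 2, neg=4
  expect_equal(ov$rank[ov$method == "pos"], 1L)
  expect_equal(sort(ov$rank[ov$method %in% c("a", "b")]), c(2L, 2L))
  expect_equal(ov$rank[ov$method == "neg"], 4L)
})

test_that("all-missing methods rank last", {
  tb <- toy_score_table() %>% normalize_scores()
  tb$normalized$value[tb$normalized$method == "m"] <- NA
  tb <- overall_score(tb)
  ov <- tb$overall
  expect_true(is.na(ov$overall[ov$method == "m"]))
  expect_equal(ov$rank[ov$method == "m"], 3L)
})

test_that("subtask collation averages overall scores and flags partial coverage", {
  mk <- function(vals, task) {
    tb <- new_score_table(
      raw = tibble::tibble(dataset = "d", method = names(vals),
                           metric = "m", value = unname(vals)),
      roles = tibble::tibble(
        method = names(vals),
        role = c("positive_control", "negative_control",
                 rep("method", length(vals) - 2))),
      orientations = tibble::tibble(metric = "m", orientation = "maximize"),
      task = task) %>% normalize_scores() %>% overall_score()
    tb
  }
  t1 <- mk(c(pos = 1, neg = 0, a = 0.8), "s1")
  t2 <- mk(c(pos = 1, neg = 0, a = 0.6), "s2")
  out <- collate_subtasks(list(t1, t2))
  expect_equal(out$score[out$method == "a"], 0.7)
  expect_false(out$partial[out$method == "a"])

  t3 <- mk(c(pos = 1, neg = 0, b = 0.9), "s2")
  out2 <- collate_subtasks(list(t1, t3))
  expect_equal(out2$score[out2$method == "b"], 0.9)
  expect_true(out2$partial[out2$method == "b"])

  # idempotence on identical tables
  out3 <- collate_subtasks(list(t1, t1))
  expect_equal(out3$score[out3$method == "a"], 0.8)
})

test_that("results export/import round-trips including missing values", {
  t <- dummy_task(n_methods = 1, n_metrics = 2, failing_method = TRUE)
  tb <- suppressMessages(benchmark_task(t, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  export_results(tb, t, path)
  txt <- paste(readLines(path), collapse = "")
  expect_match(txt, "null")  # NAs serialized as null
  r <- import_results(path)
  expect_equal(r$raw, tb$raw)
  expect_equal(r$normalized$value, tb$normalized$value)
  expect_equal(r$overall$rank, tb$overall$rank)
  expect_equal(r$seed, tb$seed)
  expect_true(validate_results_json(jsonlite::read_json(path,
                                                        simplifyVector = TRUE)))
})

test_that("structurally invalid results documents are rejected", {
  expect_error(validate_results_json(list(task = "t")),
               class = "scbench_validation_error")
  expect_error(
    validate_results_json(list(schema_version = "1.0", task = "t",
                               components = list(methods = list()),
                               raw = data.frame(x = 1))),
    class = "scbench_validation_error")
})

test_that("tidy and glance summarize score tables", {
  t <- dummy_task(n_methods = 2, n_metrics = 2)
  tb <- benchmark_task(t, seed = 5)
  td <- tidy(tb)
  expect_true(all(c("raw", "normalized", "role", "orientation", "rank") %in%
                    names(td)))
  expect_equal(nrow(td), nrow(tb$raw))
  gl <- glance(tb)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$best_method, "m2")  # higher raw value than m1
})

test_that("autoplot returns ggplot objects", {
  t <- dummy_task(n_methods = 1, n_metrics = 2)
  tb <- benchmark_task(t, seed = 5)
  expect_s3_class(autoplot(tb), "ggplot")
  expect_s3_class(autoplot(tb, type = "overall"), "ggplot")
})
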