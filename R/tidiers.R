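#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a score table
#'
#' One row per (dataset, method, metric) with raw and (when computed)
#' normalized values, method role and metric orientation.
#'
#' @param x a `score_table`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.score_table <- function(x, ...) {
  out <- x$raw %>% rename(raw = "value")
  if (!is.null(x$normalized)) {
    out <- out %>%
      left_join(x$normalized %>% rename(normalized = "value"),
                by = c("dataset", "method", "metric"))
  }
  out <- out %>%
    left_join(x$roles, by = "method") %>%
    left_join(x$orientations, by = "metric")
  if (!is.null(x$overall)) {
    out <- out %>% left_join(x$overall, by = c("dataset", "method"))
  }
  out
}

#' One-row summary of a score table
#'
#' @param x a `score_table`.
#' @param ... unused.
#' @return a one-row tibble: task, counts, seed, and the top-ranked
#'   non-control method (when ranks are available).
#' @export
glance.score_table <- function(x, ...) {
  best <- NA_character_
  best_score <- NA_real_
  if (!is.null(x$overall)) {
    controls <- x$roles$method[x$roles$role != "method"]
    cand <- x$overall %>%
      filter(!.data$method %in% controls, !is.na(.data$overall)) %>%
      group_by(.data$method) %>%
      summarise(score = mean(.data$overall), .groups = "drop") %>%
      arrange(desc(.data$score))
    if (nrow(cand)) {
      best <- cand$method[1]
      best_score <- cand$score[1]
    }
  }
  tibble(task = x$task,
         n_datasets = dplyr::n_distinct(x$raw$dataset),
         n_methods = dplyr::n_distinct(x$raw$method),
         n_metrics = dplyr::n_distinct(x$raw$metric),
         best_method = best, best_overall = best_score,
         seed = x$seed)
}

#' Plot a score table
#'
#' `type = "normalized"`: heatmap of normalized scores (method x metric,
#' faceted by dataset). `type = "overall"`: per-dataset bar chart of
#' overall scores with controls highlighted.
#'
#' @param object a `score_table`.
#' @param type what to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.score_table <- function(object, type = c("normalized", "overall"),
                                 ...) {
  type <- match.arg(type)
  if (type == "normalized") {
    if (is.null(object$normalized)) {
      abort("run normalize_scores() first", class = "scbench_configuration_error")
    }
    df <- object$normalized
    ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$method,
                                     fill = .data$value)) +
      ggplot2::geom_tile() +
      ggplot2::facet_wrap(~dataset) +
      ggplot2::scale_fill_viridis_c(na.value = "grey85") +
      ggplot2::labs(title = object$task, fill = "normalized") +
      ggplot2::theme_minimal()
  } else {
    if (is.null(object$overall)) {
      abort("run overall_score() first", class = "scbench_configuration_error")
    }
    df <- object$overall %>% left_join(object$roles, by = "method")
    ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$method, .data$overall),
                                     y = .data$overall, fill = .data$role)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::facet_wrap(~dataset) +
      ggplot2::labs(title = object$task, x = NULL, y = "overall score") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
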