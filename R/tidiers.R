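#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x A `fastmpn_model`.
#' @param ... Unused.
#' @return The per-epoch training log in long form: `epoch`, `metric`
#'   (`train_loss`, `aggregate`, `micro_<task>`, `macro_<task>`), `value`.
#' @method tidy fastmpn_model
#' @export
tidy.fastmpn_model <- function(x, ...) {
  tidyr::pivot_longer(x$log, cols = -"epoch", names_to = "metric", values_to = "value")
}

#' @rdname tidy.fastmpn_model
#' @return `glance()` returns a one-row tibble: vocabulary size, edge count,
#'   parameter total, epochs run, best epoch and its validation aggregate.
#' @method glance fastmpn_model
#' @export
glance.fastmpn_model <- function(x, ...) {
  counts <- count_parameters(x$vocab, x$registry, x$schema, x$model_config)
  tibble::tibble(
    n_vocab = x$vocab$n,
    n_edges = x$registry$e_count,
    n_parameters = counts$total,
    n_tasks = length(schema_tasks(x$schema)),
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_aggregate = if ("aggregate" %in% names(x$log) && nrow(x$log) > 0) {
      max(x$log$aggregate, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Tidy an evaluation report
#'
#' @param x A `fastmpn_eval`.
#' @param ... Unused.
#' @return `tidy()` returns the per-task score table (`task`, `micro_f1`,
#'   `macro_f1`, `n_documents`); `glance()` a one-row tibble with the
#'   aggregate.
#' @method tidy fastmpn_eval
#' @export
tidy.fastmpn_eval <- function(x, ...) {
  x$tasks
}

#' @rdname tidy.fastmpn_eval
#' @method glance fastmpn_eval
#' @export
glance.fastmpn_eval <- function(x, ...) {
  tibble::tibble(
    aggregate = x$aggregate,
    n_tasks = nrow(x$tasks),
    n_scores = 2L * nrow(x$tasks)
  )
}

#' Plot training curves
#'
#' Train loss and (when a validation corpus was supplied) the per-task
#' validation F1 trajectories, one panel per metric family.
#'
#' @param object A `fastmpn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fastmpn_model
#' @export
autoplot.fastmpn_model <- function(object, ...) {
  long <- tidy(object)
  long$family <- dplyr::case_when(
    long$metric == "train_loss" ~ "train loss",
    long$metric == "aggregate" ~ "validation aggregate",
    startsWith(long$metric, "micro_") ~ "validation micro-F1",
    startsWith(long$metric, "macro_") ~ "validation macro-F1"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-task evaluation scores
#'
#' @param object A `fastmpn_eval`.
#' @param ... Unused.
#' @return A ggplot object: micro and macro F1 per task.
#' @method autoplot fastmpn_eval
#' @export
autoplot.fastmpn_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$tasks, cols = c("micro_f1", "macro_f1"),
                              names_to = "average", values_to = "f1")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$task, y = .data$f1,
                                     fill = .data$average)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$aggregate, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "F1", fill = NULL,
                  subtitle = sprintf("aggregate = %.4f", object$aggregate)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
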