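#' Micro- and macro-averaged F1
#'
#' `micro_f1()` pools true-positive, false-positive and false-negative counts
#' over all classes before forming F1; for single-label multiclass prediction
#' this equals plain accuracy. `macro_f1()` averages per-class F1 without
#' weighting, which is the score sensitive to minority classes under severe
#' class imbalance. By default the average runs over the classes present in
#' truth or predictions; pass `classes` to average over a full class registry
#' instead. A per-class F1 whose precision+recall denominator is zero is
#' defined as 0.
#'
#' @param truth,predicted Equal-length vectors of class labels (any atomic
#'   type; compared by value).
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' micro_f1(c(0, 0, 1, 2), c(0, 1, 1, 2))   # 3 of 4 pooled -> 0.75
#' macro_f1(c(0, 0, 1, 2), c(0, 1, 1, 2))   # (2/3 + 2/3 + 1) / 3
micro_f1 <- function(truth, predicted) {
  check_eval_input(truth, predicted)
  # single-label multiclass: pooled TP = matches, pooled FP = FN = mismatches,
  # so micro-F1 reduces to accuracy
  tp <- sum(truth == predicted)
  fp <- sum(truth != predicted)
  fn <- fp
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(0)
  2 * tp / denom
}

#' @rdname micro_f1
#' @param classes Optional class universe for the macro average; defaults to
#'   the classes appearing in `truth` or `predicted`.
#' @export
macro_f1 <- function(truth, predicted, classes = NULL) {
  check_eval_input(truth, predicted)
  if (is.null(classes)) {
    classes <- sort(unique(c(truth, predicted)))
  }
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    denom <- 2 * tp + fp + fn
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  if (length(f1s) == 0L) return(0)
  mean(f1s)
}

check_eval_input <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_config("truth and predicted must have equal length")
  }
  if (length(truth) == 0L) {
    stop_config("cannot score an empty prediction set")
  }
  invisible(TRUE)
}

#' Aggregate micro/macro F1 scores across tasks
#'
#' The unweighted arithmetic mean of all supplied scores — with six tasks and
#' both F1 variants this is the 12-score comparison statistic. It is a model
#' comparison convenience with no clinical meaning of its own.
#'
#' @param scores Numeric vector of F1 scores.
#' @return Scalar mean.
#' @export
aggregate_scores <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) stop_config("no scores to aggregate")
  mean(scores)
}

#' Evaluate a fitted model on a labeled corpus
#'
#' Predicts every document, then scores each task on the documents whose truth
#' label for that task is observed. Produces per-task micro/macro F1, the
#' aggregate mean of all listed scores, a per-class precision/recall/F1 table
#' and confusion counts.
#'
#' @param model A `fastmpn_model`.
#' @param corpus A labeled corpus tibble.
#' @return A `fastmpn_eval`: list with `tasks` (tibble: `task`, `micro_f1`,
#'   `macro_f1`, `n_documents`), `aggregate`, `per_class` (tibble: `task`,
#'   `class`, `precision`, `recall`, `f1`, `support`, `predicted_count`) and
#'   `confusion` (named list of truth x predicted contingency tables).
#' @export
evaluate_model <- function(model, corpus) {
  stopifnot(inherits(model, "fastmpn_model"))
  pred <- stats::predict(model, corpus)
  tasks <- schema_tasks(model$schema)

  task_rows <- list(); class_rows <- list(); confusion <- list()
  for (task in tasks) {
    if (!task %in% names(corpus)) next
    truth <- as.character(corpus[[task]])
    obs <- !is.na(truth)
    if (!any(obs)) next
    p <- pred[[task]][obs]; tr <- truth[obs]
    task_rows[[task]] <- tibble::tibble(
      task = task,
      micro_f1 = micro_f1(tr, p),
      macro_f1 = macro_f1(tr, p),
      n_documents = sum(obs)
    )
    classes <- sort(unique(c(tr, p)))
    class_rows[[task]] <- dplyr::bind_rows(lapply(classes, function(cl) {
      tp <- sum(tr == cl & p == cl)
      fp <- sum(tr != cl & p == cl)
      fn <- sum(tr == cl & p != cl)
      tibble::tibble(
        task = task, class = cl,
        precision = if (tp + fp == 0) 0 else tp / (tp + fp),
        recall = if (tp + fn == 0) 0 else tp / (tp + fn),
        f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
        support = sum(tr == cl),
        predicted_count = sum(p == cl)
      )
    }))
    confusion[[task]] <- table(truth = tr, predicted = p)
  }
  tasks_tbl <- dplyr::bind_rows(task_rows)
  if (nrow(tasks_tbl) == 0L) stop_config("corpus has no observed labels for any task")
  structure(
    list(
      tasks = tasks_tbl,
      aggregate = aggregate_scores(c(tasks_tbl$micro_f1, tasks_tbl$macro_f1)),
      per_class = dplyr::bind_rows(class_rows),
      confusion = confusion
    ),
    class = "fastmpn_eval"
  )
}

#' @export
print.fastmpn_eval <- function(x, ...) {
  cat("<fastmpn_eval> aggregate = ", sprintf("%.4f", x$aggregate), "\n", sep = "")
  print(x$tasks)
  invisible(x)
}
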