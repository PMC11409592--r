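#' Read a corpus from JSON Lines
#'
#' One record per line, UTF-8, fields `doc_id` (string), `text` (string) and
#' `labels` (object mapping task name to class string, or null for a missing
#' label). Records are returned in file order; class labels absent from the
#' schema are rejected, as are duplicate `doc_id`s.
#'
#' @param path Path to a `.jsonl` corpus file.
#' @param schema A `fastmpn_schema` describing the tasks and their classes.
#' @return A tibble with columns `doc_id`, `text`, and one character column per
#'   schema task (`NA` where the label is missing).
#' @export
read_corpus <- function(path, schema) {
  stopifnot(inherits(schema, "fastmpn_schema"))
  if (!file.exists(path)) stop_io("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tasks <- schema_tasks(schema)

  empty <- tibble::tibble(doc_id = character(), text = character())
  for (task in tasks) empty[[task]] <- character()
  if (length(lines) == 0L) return(empty)

  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop_parse("malformed JSON on line ", i, ": ", conditionMessage(e))
      }
    )
    if (!is.list(rec) || is.null(rec$doc_id) || is.null(rec$text)) {
      stop_parse("line ", i, ": record must have doc_id and text fields")
    }
    labels <- rec$labels %||% list()
    row <- list(doc_id = as.character(rec$doc_id), text = as.character(rec$text))
    for (task in tasks) {
      val <- labels[[task]]
      if (is.null(val)) {
        row[[task]] <- NA_character_
      } else {
        val <- as.character(val)
        if (!val %in% schema[[task]]) {
          stop_schema("line ", i, ": task '", task, "' has label '", val,
                      "' not present in the schema")
        }
        row[[task]] <- val
      }
    }
    extra <- setdiff(names(labels), tasks)
    if (length(extra) > 0L) {
      stop_schema("line ", i, ": unknown task '", extra[1], "' in labels")
    }
    records[[i]] <- tibble::as_tibble(row)
  }
  out <- dplyr::bind_rows(records)
  if (anyDuplicated(out$doc_id)) {
    stop_parse("duplicate doc_id '", out$doc_id[duplicated(out$doc_id)][1], "' in ", path)
  }
  out
}

#' @rdname read_corpus
#' @param corpus A corpus tibble (`doc_id`, `text`, one column per task).
#' @export
write_corpus <- function(corpus, path, schema) {
  stopifnot(is.data.frame(corpus), inherits(schema, "fastmpn_schema"))
  tasks <- schema_tasks(schema)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    labels <- list()
    for (task in tasks) {
      val <- if (task %in% names(corpus)) corpus[[task]][i] else NA_character_
      labels[[task]] <- if (is.na(val)) NULL else as.character(val)
    }
    rec <- list(doc_id = corpus$doc_id[i], text = corpus$text[i], labels = labels)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Write and read prediction tables
#'
#' The CSV layout is `doc_id`, one column per task holding the argmax class
#' string, then one column per task (suffixed `_prob`) holding that class's
#' probability written with 6 decimal places.
#'
#' @param predictions A tibble as returned by [predict.fastmpn_model()]:
#'   `doc_id`, `<task>`, `<task>_prob` for every task.
#' @param path Output path.
#' @param schema A `fastmpn_schema`.
#' @export
write_predictions <- function(predictions, path, schema) {
  stopifnot(is.data.frame(predictions), inherits(schema, "fastmpn_schema"))
  tasks <- schema_tasks(schema)
  need <- c("doc_id", tasks, paste0(tasks, "_prob"))
  missing_cols <- setdiff(need, names(predictions))
  if (length(missing_cols) > 0L) {
    stop_config("predictions are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- predictions[need]
  for (task in tasks) {
    out[[paste0(task, "_prob")]] <- sprintf("%.6f", out[[paste0(task, "_prob")]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, schema) {
  if (!file.exists(path)) stop_io("predictions file not found: ", path)
  tasks <- schema_tasks(schema)
  spec <- c(list(doc_id = readr::col_character()),
            stats::setNames(rep(list(readr::col_character()), length(tasks)), tasks),
            stats::setNames(rep(list(readr::col_double()), length(tasks)),
                            paste0(tasks, "_prob")))
  readr::read_csv(path, col_types = do.call(readr::cols, spec), progress = FALSE)
}

CHECKPOINT_VERSION <- 1L

#' Save and restore model checkpoints
#'
#' A checkpoint stores the complete fitted model — parameter tables, vocabulary,
#' edge registry, schema, configuration, and training log — such that
#' `load_checkpoint(save_checkpoint(m))` reproduces every parameter bit-exactly
#' and evaluation after reload matches evaluation before saving.
#'
#' @param model A `fastmpn_model` (see [fastmpn_fit()]).
#' @param path Checkpoint path (RDS serialization).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fastmpn_model"))
  payload <- list(
    format = "fastmpn_checkpoint",
    version = CHECKPOINT_VERSION,
    model = model
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the `fastmpn_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop(errorCondition(
      paste0("cannot read checkpoint '", path, "': ", conditionMessage(e)),
      class = c("fastmpn_checkpoint_error", "fastmpn_error")
    ))
  })
  if (!is.list(payload) || !identical(payload$format, "fastmpn_checkpoint")) {
    stop(errorCondition(
      paste0("'", path, "' is not a fastmpn checkpoint"),
      class = c("fastmpn_checkpoint_error", "fastmpn_error")
    ))
  }
  if (!identical(payload$version, CHECKPOINT_VERSION)) {
    stop(errorCondition(
      paste0("checkpoint version ", payload$version,
             " is incompatible with this build (expected ", CHECKPOINT_VERSION, ")"),
      class = c("fastmpn_checkpoint_error", "fastmpn_error")
    ))
  }
  payload$model
}

#' Write and read evaluation metrics as JSON
#'
#' Layout: `{task: {micro_f1, macro_f1}, ..., aggregate}`.
#'
#' @param report A `fastmpn_eval` (see [evaluate_model()]).
#' @param path Output path.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "fastmpn_eval"))
  out <- list()
  for (i in seq_len(nrow(report$tasks))) {
    out[[report$tasks$task[i]]] <- list(
      micro_f1 = report$tasks$micro_f1[i],
      macro_f1 = report$tasks$macro_f1[i]
    )
  }
  out$aggregate <- report$aggregate
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop_io("metrics file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a per-class precision/recall/F1 report as CSV
#'
#' @rdname write_metrics
#' @export
write_class_report <- function(report, path) {
  stopifnot(inherits(report, "fastmpn_eval"))
  readr::write_csv(report$per_class, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
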