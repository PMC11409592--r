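#' Define a label schema
#'
#' A label schema is the ordered set of classification tasks a corpus is
#' annotated with, together with the ordered class registry of each task.
#' Task order is stable and defines the order of the model's output heads;
#' class order within a task defines the class index used internally.
#'
#' @param ... Named character vectors, one per task, e.g.
#'   `label_schema(grade = c("1", "2", "3"), behavior = c("benign", "malignant"))`.
#' @return A `fastmpn_schema` object: a named list of character class vectors.
#' @export
#' @examples
#' schema <- label_schema(grade = c("1", "2", "3"), laterality = c("left", "right"))
#' schema_tasks(schema)
label_schema <- function(...) {
  classes <- list(...)
  if (length(classes) == 0L) {
    stop_config("a label schema needs at least one task")
  }
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stop_config("every task in a label schema must be named")
  }
  if (anyDuplicated(names(classes))) {
    stop_config("duplicate task names in label schema")
  }
  for (task in names(classes)) {
    cls <- classes[[task]]
    if (!is.character(cls) || length(cls) == 0L) {
      stop_config("task '", task, "': class list must be a non-empty character vector")
    }
    if (anyDuplicated(cls)) {
      stop_config("task '", task, "': duplicate class labels")
    }
  }
  structure(lapply(classes, as.character), class = "fastmpn_schema")
}

#' @rdname label_schema
#' @param schema A `fastmpn_schema`.
#' @export
schema_tasks <- function(schema) {
  names(schema)
}

#' @rdname label_schema
#' @param task A task name.
#' @export
schema_classes <- function(schema, task) {
  if (!task %in% names(schema)) {
    stop_config("unknown task '", task, "'")
  }
  schema[[task]]
}

#' @export
print.fastmpn_schema <- function(x, ...) {
  cat("<fastmpn_schema> ", length(x), " task(s)\n", sep = "")
  for (task in names(x)) {
    cat("  ", task, ": ", length(x[[task]]), " classes\n", sep = "")
  }
  invisible(x)
}

#' Read and write label schemas as JSON
#'
#' The on-disk form is a JSON object mapping each task name to its ordered
#' array of class-label strings.
#'
#' @param path File path.
#' @return `read_schema()` returns a `fastmpn_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) {
    stop_io("schema file not found: ", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) && !is.character(raw)) {
    stop_parse("schema JSON must be an object of task -> class array: ", path)
  }
  do.call(label_schema, as.list(raw))
}

#' @rdname read_schema
#' @param schema A `fastmpn_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "fastmpn_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# classed conditions used across the package ---------------------------------

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("fastmpn_config_error", "fastmpn_error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("fastmpn_parse_error", "fastmpn_error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("fastmpn_schema_error", "fastmpn_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("fastmpn_io_error", "fastmpn_error")))
}

stop_structural <- function(...) {
  stop(errorCondition(paste0(...), class = c("fastmpn_structural_error", "fastmpn_error")))
}
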