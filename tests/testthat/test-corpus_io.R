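test_that("corpus JSON Lines reader enforces schema and reports line numbers", {
  schema <- toy_schema()
  path <- withr::local_tempfile(fileext = ".jsonl")

  writeLines(character(0), path)
  empty <- read_corpus(path, schema)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("doc_id", "text", "grade", "behavior"))

  writeLines('{"doc_id":"a","text":"histologic grade: 3","labels":{"grade":"3"}}', path)
  one <- read_corpus(path, schema)
  expect_equal(one$doc_id, "a")
  expect_equal(one$grade, "3")
  expect_true(is.na(one$behavior))

  writeLines('{"doc_id":"a","text":"x","labels":{"grade":"99"}}', path)
  err <- expect_error(read_corpus(path, schema), class = "fastmpn_schema_error")
  expect_match(conditionMessage(err), "grade")
  expect_match(conditionMessage(err), "99")

  writeLines(c('{"doc_id":"a","text":"x","labels":{}}', "{not json"), path)
  err <- expect_error(read_corpus(path, schema), class = "fastmpn_parse_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(rep('{"doc_id":"a","text":"x","labels":{}}', 2), path)
  expect_error(read_corpus(path, schema), class = "fastmpn_parse_error")
})

test_that("corpus writer and reader are inverse and reads are repeatable", {
  schema <- toy_schema()
  corpus <- toy_corpus()
  corpus$behavior[2] <- NA  # missing label encoded as null
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path, schema)
  back1 <- read_corpus(path, schema)
  back2 <- read_corpus(path, schema)
  expect_identical(back1, back2)
  expect_equal(back1$doc_id, corpus$doc_id)
  expect_equal(back1$text, corpus$text)
  expect_equal(back1$grade, corpus$grade)
  expect_equal(back1$behavior, corpus$behavior)
})

test_that("prediction CSV has the stated column layout and round-trips to 6 dp", {
  schema <- toy_schema()
  path <- withr::local_tempfile(fileext = ".csv")

  empty <- tibble::tibble(doc_id = character(), grade = character(),
                          behavior = character(), grade_prob = numeric(),
                          behavior_prob = numeric())
  write_predictions(empty, path, schema)
  expect_equal(readLines(path), "doc_id,grade,behavior,grade_prob,behavior_prob")

  pred <- tibble::tibble(
    doc_id = c("a", "b"),
    grade = c("3", "1"), behavior = c("malignant", "benign"),
    grade_prob = c(0.9876543, 0.5), behavior_prob = c(1 / 3, 0.25)
  )
  write_predictions(pred, path, schema)
  expect_equal(length(strsplit(readLines(path)[2], ",")[[1]]), 5L)  # 1 + 2 + 2
  back <- read_predictions(path, schema)
  expect_equal(back$grade, pred$grade)
  expect_equal(back$grade_prob, pred$grade_prob, tolerance = 1e-6)
  expect_equal(back$behavior_prob, pred$behavior_prob, tolerance = 1e-6)
})

test_that("checkpoints round-trip parameters bit-exactly and reject damage", {
  pipe <- toy_pipeline()
  model <- train_model(pipe$encoded, pipe$registry, pipe$vocab, pipe$schema,
                       model = model_config(w = 4),
                       train = train_config(epochs = 2, seed = 3, batch_size = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$log, model$log)
  expect_identical(back$model_config, model$model_config)

  # truncated file -> incompatibility error
  bytes <- readBin(path, "raw", n = file.size(path))
  writeBin(bytes[seq_len(20)], path)
  expect_error(load_checkpoint(path), class = "fastmpn_checkpoint_error")

  # wrong payload -> incompatibility error
  saveRDS(list(format = "something_else"), path)
  expect_error(load_checkpoint(path), class = "fastmpn_checkpoint_error")
})

test_that("a reloaded checkpoint evaluates identically to the model before saving", {
  cfg <- generator_config(n_docs = 150, seed = 31)
  corpus <- generate_corpus(cfg)
  schema <- synthetic_schema(cfg)
  model <- fastmpn_fit(corpus[1:120, ], schema, validation = corpus[121:150, ],
                       gow = gow_config(d = 2),
                       model = model_config(w = 8),
                       train = train_config(epochs = 3, seed = 5, learning_rate = 0.01))
  before <- evaluate_model(model, corpus[121:150, ])
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  after <- evaluate_model(load_checkpoint(path), corpus[121:150, ])
  expect_identical(tidy(after), tidy(before))
  expect_identical(after$aggregate, before$aggregate)
})

test_that("metrics JSON is internally consistent and round-trips", {
  pipe <- toy_pipeline()
  model <- train_model(pipe$encoded, pipe$registry, pipe$vocab, pipe$schema,
                       model = model_config(w = 4),
                       train = train_config(epochs = 1, seed = 3, batch_size = 4))
  report <- evaluate_model(model, pipe$corpus)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(report, path)
  back <- read_metrics(path)
  listed <- unlist(lapply(back[setdiff(names(back), "aggregate")],
                          function(x) c(x$micro_f1, x$macro_f1)))
  expect_equal(back$aggregate, mean(listed), tolerance = 1e-12)
  expect_equal(back$aggregate, report$aggregate, tolerance = 1e-12)
})

test_that("schema JSON round-trips with task and class order preserved", {
  schema <- toy_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(schema, path)
  expect_identical(read_schema(path), schema)
})
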