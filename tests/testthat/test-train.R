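test_that("multitask loss: perfect predictions, uniform closed form, summation oracle", {
  labels <- list(a = c(1L, 2L), b = c(1L, NA))
  perfect <- list(
    list(a = c(1, 0, 0), b = c(1, 0)),
    list(a = c(0, 1, 0), b = c(0.5, 0.5))
  )
  expect_equal(multitask_loss(perfect, labels), 0, tolerance = 1e-12)

  uniform <- list(
    list(a = rep(1 / 3, 3), b = rep(1 / 2, 2)),
    list(a = rep(1 / 3, 3), b = rep(1 / 2, 2))
  )
  # per-task term ln K; the masked b label of doc 2 contributes exactly 0
  expect_equal(multitask_loss(uniform, labels),
               (2 * log(3) + 1 * log(2)) / 2, tolerance = 1e-12)

  withr::with_seed(4, {
    preds <- lapply(1:3, function(i) {
      a <- runif(3); b <- runif(2)
      list(a = a / sum(a), b = b / sum(b))
    })
    labs <- list(a = c(2L, 1L, 3L), b = c(NA, 2L, 1L))
    hand <- -(log(preds[[1]]$a[2]) + log(preds[[2]]$a[1]) + log(preds[[3]]$a[3]) +
                log(preds[[2]]$b[2]) + log(preds[[3]]$b[1])) / 3
    expect_equal(multitask_loss(preds, labs), hand, tolerance = 1e-12)
  })

  expect_error(multitask_loss(uniform, list(a = c(NA, NA), b = c(NA, NA))),
               class = "fastmpn_config_error")
})

test_that("batches partition the corpus, keep the short tail, and shuffle by seed", {
  cfg <- generator_config(n_docs = 10, seed = 2)
  corpus <- generate_corpus(cfg)
  schema <- synthetic_schema(cfg)
  vocab <- build_vocabulary(corpus)
  enc <- encode_corpus(corpus, vocab, schema)
  reg <- build_edge_registry(enc, vocab, gow_config(d = 1))

  b <- make_batches(enc, reg, batch_size = 4, seed = 1, shuffle = TRUE)
  expect_equal(vapply(b, function(x) x$n_docs, integer(1)), c(4L, 4L, 2L))
  # union of batches equals the corpus as a multiset
  expect_setequal(unlist(lapply(b, function(x) x$doc_id)), enc$doc_id)

  b_noshuf <- make_batches(enc, reg, batch_size = 4, seed = 1, shuffle = FALSE)
  expect_equal(unlist(lapply(b_noshuf, function(x) x$doc_id)), enc$doc_id)

  b2 <- make_batches(enc, reg, batch_size = 4, seed = 1, shuffle = TRUE)
  expect_identical(lapply(b, function(x) x$doc_id), lapply(b2, function(x) x$doc_id))

  # padded entries of the token matrix are the PAD index
  lens <- vapply(seq_len(b[[1]]$n_docs), function(i) {
    sum(b[[1]]$node_doc == i)
  }, integer(1))
  for (i in seq_along(lens)) {
    if (lens[i] < ncol(b[[1]]$token_mat)) {
      expect_true(all(b[[1]]$token_mat[i, (lens[i] + 1):ncol(b[[1]]$token_mat)] == 0L))
    }
  }
})

test_that("a tiny model memorizes a 2-document toy task", {
  schema <- label_schema(t = c("pos", "neg"))
  corpus <- tibble::tibble(
    doc_id = c("p", "n"),
    text = c("alpha beta alpha", "gamma delta gamma"),
    t = c("pos", "neg")
  )
  model <- fastmpn_fit(corpus, schema,
                       gow = gow_config(d = 1),
                       model = model_config(w = 8),
                       train = train_config(epochs = 200, seed = 7, batch_size = 2,
                                            learning_rate = 0.05, shuffle = FALSE))
  expect_lt(model$log$train_loss[nrow(model$log)], 0.01)
  pred <- predict(model, corpus)
  expect_equal(pred$t, c("pos", "neg"))
})

test_that("training is seed-deterministic: same seed gives bit-identical logs", {
  cfg <- generator_config(n_docs = 80, seed = 17)
  corpus <- generate_corpus(cfg)
  schema <- synthetic_schema(cfg)
  fit_once <- function() {
    fastmpn_fit(corpus[1:60, ], schema, validation = corpus[61:80, ],
                gow = gow_config(d = 2),
                model = model_config(w = 6, dropout = 0.25),
                train = train_config(epochs = 3, seed = 99, learning_rate = 0.01))
  }
  m1 <- fit_once(); m2 <- fit_once()
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("fixed-embedding training leaves the embedding table bit-identical", {
  pipe <- toy_pipeline(w = 6)
  model <- train_model(pipe$encoded, pipe$registry, pipe$vocab, pipe$schema,
                       model = model_config(w = 6),
                       train = train_config(epochs = 5, seed = 21, batch_size = 2,
                                            trainable_embedding = FALSE,
                                            learning_rate = 0.05))
  init <- withr::with_seed(21, init_params(pipe$vocab, pipe$registry, pipe$schema,
                                           model_config(w = 6)))
  expect_identical(model$params$embedding, init$embedding)
  expect_false(identical(model$params$edge_weights, init$edge_weights))
  expect_false(identical(model$params$heads, init$heads))
})

test_that("ST-mode loss equals MT-mode loss restricted to that task", {
  pipe <- toy_pipeline(w = 5)
  batches <- make_batches(pipe$encoded, pipe$registry, batch_size = 4, shuffle = FALSE)
  b <- batches[[1]]
  mt <- fastmpn:::batch_forward(pipe$params, b, pipe$schema, pipe$config)
  st_grade <- fastmpn:::batch_forward(pipe$params, b, pipe$schema, pipe$config,
                                      tasks = "grade")
  st_behavior <- fastmpn:::batch_forward(pipe$params, b, pipe$schema, pipe$config,
                                         tasks = "behavior")
  expect_equal(st_grade$loss + st_behavior$loss, mt$loss, tolerance = 1e-12)
  expect_gte(st_grade$loss, 0)
})

test_that("ST mode rejects unknown tasks and PAD embedding row stays zero", {
  pipe <- toy_pipeline(w = 4)
  expect_error(
    train_model(pipe$encoded, pipe$registry, pipe$vocab, pipe$schema,
                model = model_config(w = 4),
                train = train_config(epochs = 1, mode = "ST", st_task = "nope")),
    class = "fastmpn_config_error"
  )
  model <- train_model(pipe$encoded, pipe$registry, pipe$vocab, pipe$schema,
                       model = model_config(w = 4),
                       train = train_config(epochs = 3, seed = 2, batch_size = 2))
  expect_equal(model$params$embedding[1, ], rep(0, 4))
})

test_that("missing labels are masked: training runs on partially labeled corpora", {
  corpus <- toy_corpus()
  corpus$behavior <- NA_character_
  corpus$behavior[1] <- "malignant"
  schema <- toy_schema()
  model <- fastmpn_fit(corpus, schema,
                       gow = gow_config(d = 1),
                       model = model_config(w = 4),
                       train = train_config(epochs = 2, seed = 1, batch_size = 2))
  expect_true(all(is.finite(model$log$train_loss)))
})
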