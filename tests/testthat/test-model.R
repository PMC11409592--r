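test_that("max aggregation reproduces single-edge and identity cases", {
  # one node, self edge with weight 1: message is the node's own embedding
  fix <- random_graph_fixture(n_nodes = 1, n_words = 3, d = 1, w = 4, seed = 2)
  p <- fix$params
  p$edge_weights[] <- 1
  m <- message_max(fix$graph, p)
  expect_equal(m, fastmpn:::node_states(fix$graph, p))

  # a single incoming term is the dimension-wise max, sign preserved
  # (self loops off so the only incoming edge of node 2 is a -> n)
  v <- new_test_vocab(2)
  enc <- tibble::tibble(doc_id = "1", tokens = list(c(2L, 3L)), n_tokens = 2L)
  reg <- build_edge_registry(enc, v, gow_config(d = 1, self_loops = FALSE))
  g <- build_document_graph(c(2L, 3L), reg)
  schema <- label_schema(t = c("a", "b"))
  p2 <- init_params(v, reg, schema, model_config(w = 2))
  p2$embedding[3, ] <- c(1, -1)            # word at position 1 (index 2)
  p2$edge_weights[] <- 0
  p2$edge_weights[fastmpn:::registry_lookup(reg, 2L, 3L) + 1L] <- 2
  m <- message_max(g, p2)
  expect_equal(m[2, ], c(2, -2))
})

test_that("max aggregation equals a per-node nested-loop oracle on random graphs", {
  for (seed in 1:5) {
    fix <- random_graph_fixture(n_nodes = 5, n_words = 4, d = 2, w = 6, seed = seed)
    expect_equal(message_max(fix$graph, fix$params),
                 oracle_message_max(fix$graph, fix$params))
  }
})

test_that("dense aggregation: annihilation, identity, and the explicit-sum oracle", {
  fix <- random_graph_fixture(n_nodes = 6, n_words = 4, d = 2, w = 5, seed = 3)
  p <- fix$params
  p0 <- p; p0$edge_weights[] <- 0
  expect_equal(message_dense(fix$graph, p0), matrix(0, 6, 5))

  one <- random_graph_fixture(n_nodes = 1, n_words = 2, d = 1, w = 3, seed = 4)
  pone <- one$params; pone$edge_weights[] <- 1
  expect_equal(message_dense(one$graph, pone), fastmpn:::node_states(one$graph, pone))

  expect_equal(message_dense(fix$graph, p), oracle_message_sum(fix$graph, p))
})

test_that("gather-scatter aggregation is equivalent to the dense product", {
  # the architecture's stated identity between the indexed and dense forms
  worst <- 0
  for (seed in 1:25) {
    n_nodes <- withr::with_seed(seed, sample(2:50, 1))
    w <- withr::with_seed(seed + 1000, sample(1:16, 1))
    fix <- random_graph_fixture(n_nodes = n_nodes, n_words = 12, d = 3, w = w,
                                seed = seed)
    dev <- max(abs(message_sparse(fix$graph, fix$params) -
                     message_dense(fix$graph, fix$params)))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-5)
})

test_that("node update interpolates between message and previous state", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  r <- matrix(c(5, 6, 7, 8), 2, 2)
  # retention off: message replaces state
  expect_equal(node_update(m, r, use_eta = FALSE), m)

  # eta -> 1 limit recovers the old state; eta = 0.5 fixes M = r_old
  eta_big <- rep(20, 4)   # plogis(20) ~ 1
  words <- c(0L, 1L)
  expect_equal(node_update(m, r, eta_big, words, use_eta = TRUE), r, tolerance = 1e-7)
  expect_equal(node_update(r, r, rep(0, 4), words, use_eta = TRUE), r)

  # convex combination: every component lies between message and old state
  withr::with_seed(1, {
    m2 <- matrix(rnorm(20), 4, 5)
    r2 <- matrix(rnorm(20), 4, 5)
    eta_raw <- rnorm(4)
    out <- node_update(m2, r2, eta_raw, 0:3, use_eta = TRUE)
    lo <- pmin(m2, r2); hi <- pmax(m2, r2)
    expect_true(all(out >= lo - 1e-12 & out <= hi + 1e-12))
  })
})

test_that("readout heads are normalized, permutation invariant, and uniform at zero", {
  fix <- random_graph_fixture(n_nodes = 9, n_words = 5, d = 2, w = 6, seed = 7)
  states <- fastmpn:::node_states(fix$graph, fix$params)
  y <- readout(states, fix$params, fix$schema, fix$config)
  expect_equal(sum(y$t1), 1, tolerance = 1e-6)

  perm <- withr::with_seed(3, sample(nrow(states)))
  y_perm <- readout(states[perm, , drop = FALSE], fix$params, fix$schema, fix$config)
  expect_equal(y_perm, y, tolerance = 1e-12)

  p0 <- fix$params
  p0$heads$t1$V[] <- 0; p0$heads$t1$b[] <- 0
  y0 <- readout(states, p0, fix$schema, fix$config)
  expect_equal(unname(y0$t1), rep(0.5, 2))

  expect_error(readout(states[0, , drop = FALSE], fix$params, fix$schema, fix$config),
               class = "fastmpn_structural_error")
})

test_that("forward pass is identical under dense and sparse modes and deterministic", {
  pipe <- toy_pipeline(w = 8)
  g <- build_document_graph(pipe$encoded$tokens[[1]], pipe$registry)
  cfg_sparse <- model_config(w = 8, mode = "sparse_sum")
  cfg_dense <- model_config(w = 8, mode = "dense_sum")
  y1 <- forward_document(g, pipe$params, pipe$schema, cfg_sparse)
  y2 <- forward_document(g, pipe$params, pipe$schema, cfg_dense)
  for (task in names(y1)) expect_equal(y1[[task]], y2[[task]], tolerance = 1e-5)
  y3 <- forward_document(g, pipe$params, pipe$schema, cfg_sparse)
  expect_identical(y1, y3)
})

test_that("a single-token document is classified from its self-weighted embedding", {
  v <- new_test_vocab(2)
  enc <- tibble::tibble(doc_id = "1", tokens = list(2L), n_tokens = 1L)
  reg <- build_edge_registry(enc, v, gow_config(d = 1))
  schema <- label_schema(t = c("a", "b", "c"))
  cfg <- model_config(w = 3)
  p <- withr::with_seed(2, init_params(v, reg, schema, cfg))
  g <- build_document_graph(2L, reg)
  y <- forward_document(g, p, schema, cfg)
  e_self <- p$edge_weights[fastmpn:::registry_lookup(reg, 2L, 2L) + 1L]
  pooled <- e_self * p$embedding[3, ]
  z <- drop(p$heads$t$V %*% pooled) + p$heads$t$b
  expect_equal(unname(y$t), unname(exp(z - max(z)) / sum(exp(z - max(z)))),
               tolerance = 1e-12)
})

test_that("parameter counts: hand count, large-scale embedding block, enumeration oracle", {
  # N=2 word rows, w=1, no edges, one 2-class head: 2 + 0 + 0 + (2 + 2) = 6
  cfg1 <- model_config(w = 1)
  schema1 <- label_schema(t = c("a", "b"))
  counts1 <- count_parameters(2, NULL, schema1, cfg1, include_sentinels = FALSE)
  expect_equal(counts1$total, 6)

  # production-scale embedding block: 202,373 word types at w = 300
  counts2 <- count_parameters(202373, NULL, NULL, model_config(w = 300),
                              include_sentinels = FALSE)
  expect_identical(counts2$embedding, 60711900)

  # synthetic model: equals direct enumeration of every trainable entry
  pipe <- toy_pipeline(w = 5)
  counts3 <- count_parameters(pipe$vocab, pipe$registry, pipe$schema, pipe$config)
  enumerated <- length(pipe$params$embedding) + length(pipe$params$edge_weights) +
    sum(vapply(pipe$params$heads, function(h) length(h$V) + length(h$b), numeric(1)))
  expect_equal(counts3$total, enumerated)

  cfg_eta <- model_config(w = 5, use_eta = TRUE)
  p_eta <- withr::with_seed(1, init_params(pipe$vocab, pipe$registry, pipe$schema, cfg_eta))
  counts4 <- count_parameters(pipe$vocab, pipe$registry, pipe$schema, cfg_eta)
  expect_equal(counts4$total, enumerated + length(p_eta$eta_raw))
})
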