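# Small in-code fixtures shared across test files.

toy_schema <- function() {
  label_schema(
    grade = c("1", "2", "3"),
    behavior = c("benign", "malignant")
  )
}

toy_corpus <- function() {
  tibble::tibble(
    doc_id = c("d1", "d2", "d3", "d4"),
    text = c(
      "histologic grade: 3. behavior: malignant",
      "histologic grade: 1. behavior: benign",
      "histologic grade (mbr): 2. behavior: malignant",
      "grade 3 histologic. behavior: benign"
    ),
    grade = c("3", "1", "2", "3"),
    behavior = c("malignant", "benign", "malignant", "benign")
  )
}

# a tiny deterministic random pipeline: vocab, encoding, registry, params
toy_pipeline <- function(d = 2L, w = 6L, seed = 1L, mode = "sparse_sum",
                         use_eta = FALSE, activation = "identity") {
  schema <- toy_schema()
  corpus <- toy_corpus()
  vocab <- build_vocabulary(corpus)
  encoded <- encode_corpus(corpus, vocab, schema)
  registry <- build_edge_registry(encoded, vocab, gow_config(d = d))
  config <- model_config(w = w, mode = mode, use_eta = use_eta,
                         activation = activation)
  params <- withr::with_seed(seed, init_params(vocab, registry, schema, config))
  list(schema = schema, corpus = corpus, vocab = vocab, encoded = encoded,
       registry = registry, config = config, params = params)
}

# random document graph over a fresh random "vocabulary" of n_words types
random_graph_fixture <- function(n_nodes, n_words, d = 2L, w = 8L, seed = 1L) {
  withr::with_seed(seed, {
    tokens <- sample.int(n_words, n_nodes, replace = TRUE) + 1L  # skip PAD/UNK
    vocab <- new_test_vocab(n_words)
    enc <- tibble::tibble(doc_id = "g", tokens = list(tokens), n_tokens = n_nodes)
    registry <- build_edge_registry(enc, vocab, gow_config(d = d))
    graph <- build_document_graph(tokens, registry)
    schema <- label_schema(t1 = c("a", "b"))
    config <- model_config(w = w)
    params <- init_params(vocab, registry, schema, config)
    list(graph = graph, params = params, vocab = vocab, registry = registry,
         schema = schema, config = config, tokens = tokens)
  })
}

new_test_vocab <- function(n_words) {
  words <- sprintf("w%03d", seq_len(n_words))
  fastmpn:::new_vocab(
    word = c("<pad>", "<unk>", words),
    freq = c(0L, 0L, rep(1L, n_words))
  )
}

# brute-force per-node, per-dimension message oracles
oracle_message_max <- function(graph, params) {
  w <- ncol(params$embedding)
  m <- matrix(NA_real_, graph$n_nodes, w)
  for (n in seq_len(graph$n_nodes)) {
    inc <- which(graph$tgt == n)
    for (k in seq_len(w)) {
      vals <- vapply(inc, function(eix) {
        a <- graph$src[eix]
        params$edge_weights[graph$edge_id[eix] + 1L] *
          params$embedding[graph$node_words[a] + 1L, k]
      }, numeric(1))
      m[n, k] <- max(vals)
    }
  }
  m
}

oracle_message_sum <- function(graph, params) {
  w <- ncol(params$embedding)
  m <- matrix(0, graph$n_nodes, w)
  for (eix in seq_along(graph$src)) {
    a <- graph$src[eix]; n <- graph$tgt[eix]
    m[n, ] <- m[n, ] + params$edge_weights[graph$edge_id[eix] + 1L] *
      params$embedding[graph$node_words[a] + 1L, ]
  }
  m
}

# nested-loop enumeration of windowed ordered pairs in an encoded corpus
oracle_windowed_pairs <- function(token_lists, d) {
  pairs <- character(0)
  for (toks in token_lists) {
    len <- length(toks)
    if (len < 2L) next
    for (i in seq_len(len)) {
      for (j in seq_len(len)) {
        if (i != j && abs(i - j) <= d) {
          pairs <- c(pairs, paste(toks[i], toks[j], sep = "_"))
        }
      }
    }
  }
  pairs
}
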