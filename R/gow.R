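#' Graph-of-words configuration
#'
#' @param d Window distance: two token positions co-occur when they are at most
#'   `d` apart (default 2). The neighborhood size of the message pass equals
#'   the window, so `d` is the single locality parameter.
#' @param edge_min_count Minimum corpus count for an ordered word pair to get
#'   its own trainable edge weight (default 1; raise to prune rare pairs).
#' @param self_loops Register a self pair `(w, w)` for every vocabulary word
#'   and put a self edge on every node (default `TRUE`). The self edge carries
#'   the node's own state into the weighted-sum message, playing the role the
#'   reference architecture gives to its retention coefficient.
#' @return A `fastmpn_gow_config` list.
#' @export
gow_config <- function(d = 2L, edge_min_count = 1L, self_loops = TRUE) {
  d <- as.integer(d)
  edge_min_count <- as.integer(edge_min_count)
  if (is.na(d) || d < 1L) stop_config("window distance d must be an integer >= 1")
  if (is.na(edge_min_count) || edge_min_count < 1L) stop_config("edge_min_count must be >= 1")
  structure(list(d = d, edge_min_count = edge_min_count, self_loops = isTRUE(self_loops)),
            class = "fastmpn_gow_config")
}

PUBLIC_EDGE_ID <- 0L

# 0-based word pair -> numeric code, unique for a < vocab size n
pair_code <- function(a, b, n) as.numeric(a) * n + as.numeric(b)

#' Build the corpus-level edge registry
#'
#' Scans every encoded document and registers one trainable edge identifier per
#' ordered word pair `(a, n)` observed at token distance 1..d with corpus count
#' at least `edge_min_count`. When self-loops are enabled, a self pair `(w, w)`
#' is additionally registered for every vocabulary word except the padding
#' sentinel, whether or not it was observed. Identifier 0 is the public
#' (fallback) edge used at inference for pairs never seen in training;
#' identifiers 1..E are assigned in sorted pair order, so the registry is
#' deterministic for a given corpus.
#'
#' @param encoded An encoded corpus tibble (see [encode_corpus()]).
#' @param vocab A `fastmpn_vocab`.
#' @param config A `fastmpn_gow_config`.
#' @return A `fastmpn_registry` with fields `pair_a`, `pair_b` (0-based word
#'   indices in sorted order), `count`, `n_vocab`, `e_count`
#'   (= registered pairs + 1 for the public edge) and the config.
#' @export
build_edge_registry <- function(encoded, vocab, config = gow_config()) {
  stopifnot(is.data.frame(encoded), "tokens" %in% names(encoded),
            inherits(vocab, "fastmpn_vocab"), inherits(config, "fastmpn_gow_config"))
  if (nrow(encoded) == 0L) stop_config("cannot build an edge registry from an empty corpus")
  n <- vocab$n
  d <- config$d

  # ordered windowed pairs, both directions, over all documents
  codes <- vector("list", nrow(encoded) * d * 2L)
  k <- 0L
  for (doc in encoded$tokens) {
    len <- length(doc)
    if (len < 2L) next
    for (off in seq_len(min(d, len - 1L))) {
      src <- doc[seq_len(len - off)]
      tgt <- doc[seq.int(off + 1L, len)]
      k <- k + 1L; codes[[k]] <- pair_code(src, tgt, n)
      k <- k + 1L; codes[[k]] <- pair_code(tgt, src, n)
    }
  }
  codes <- unlist(codes[seq_len(k)], use.names = FALSE)
  counted <- if (length(codes) > 0L) {
    agg <- rowsum(rep(1L, length(codes)), group = codes)
    tibble::tibble(code = as.numeric(rownames(agg)), count = as.integer(agg[, 1]))
  } else {
    tibble::tibble(code = numeric(), count = integer())
  }
  counted <- counted[counted$count >= config$edge_min_count, ]

  if (config$self_loops) {
    self_words <- seq.int(UNK_INDEX, n - 1L)          # every word but PAD
    self_code <- pair_code(self_words, self_words, n)
    token_freq <- c(0L, 0L, vocab$freq[-(1:2)])       # observed count of (w,w) at distance 0
    keep <- !self_code %in% counted$code
    counted <- dplyr::bind_rows(
      counted,
      tibble::tibble(code = self_code[keep], count = token_freq[self_words[keep] + 1L])
    )
  }
  counted <- counted[order(counted$code), ]
  a <- as.integer(counted$code %/% n)
  b <- as.integer(counted$code %% n)

  structure(
    list(
      pair_a = a, pair_b = b, count = counted$count,
      code = counted$code,
      n_vocab = n,
      e_count = nrow(counted) + 1L,
      config = config
    ),
    class = "fastmpn_registry"
  )
}

#' @export
print.fastmpn_registry <- function(x, ...) {
  cat("<fastmpn_registry> ", x$e_count - 1L, " registered pairs + 1 public edge (d = ",
      x$config$d, ")\n", sep = "")
  invisible(x)
}

# edge ids (0-based; 0 = public) for ordered 0-based word pairs
registry_lookup <- function(registry, a, b) {
  idx <- match(pair_code(a, b, registry$n_vocab), registry$code)
  ids <- idx                       # registered rows occupy ids 1..E in code order
  ids[is.na(idx)] <- PUBLIC_EDGE_ID
  as.integer(ids)
}

#' Build the message-passing graph of one document
#'
#' One node per token position (embeddings are shared by word type, so repeated
#' words contribute multiply to the sum readout). Directed edges run both ways
#' between every pair of positions at distance 1..d, plus a self edge on every
#' node when self-loops are enabled. Each edge carries the registry identifier
#' of its ordered word pair, falling back to the public edge for pairs never
#' registered — this is what lets a trained model run on unseen documents.
#'
#' @param tokens Integer vector of 0-based token indices (one encoded
#'   document), or a one-row slice of an encoded corpus.
#' @param registry A `fastmpn_registry`.
#' @return A `fastmpn_graph`: list with `node_words` (0-based word index per
#'   node), `src`, `tgt` (1-based node positions), `edge_id` (0-based registry
#'   identifiers) and `n_nodes`.
#' @export
build_document_graph <- function(tokens, registry) {
  stopifnot(inherits(registry, "fastmpn_registry"))
  tokens <- as.integer(tokens)
  len <- length(tokens)
  if (len == 0L) stop_structural("cannot build a graph for an empty document")
  d <- registry$config$d

  src <- integer(0); tgt <- integer(0)
  if (len >= 2L) {
    for (off in seq_len(min(d, len - 1L))) {
      i <- seq_len(len - off)
      j <- seq.int(off + 1L, len)
      src <- c(src, i, j)
      tgt <- c(tgt, j, i)
    }
  }
  if (registry$config$self_loops) {
    src <- c(src, seq_len(len))
    tgt <- c(tgt, seq_len(len))
  }
  if (length(src) == 0L) {
    stop_structural("document graph has a node with no incoming edges (enable self_loops)")
  }
  edge_id <- registry_lookup(registry, tokens[src], tokens[tgt])
  structure(
    list(node_words = tokens, src = src, tgt = tgt, edge_id = edge_id, n_nodes = len),
    class = "fastmpn_graph"
  )
}

#' Summary counts of a document graph
#'
#' @param graph A `fastmpn_graph`.
#' @return A tibble with `n_nodes`, `n_edges` and `n_public_edges` (edges that
#'   fell back to the public identifier).
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "fastmpn_graph"))
  tibble::tibble(
    n_nodes = graph$n_nodes,
    n_edges = length(graph$src),
    n_public_edges = sum(graph$edge_id == PUBLIC_EDGE_ID)
  )
}

#' Dump an edge registry as TSV for inspection
#'
#' Columns `word_a`, `word_b`, `edge_id`, `count`, rows in identifier order.
#'
#' @param registry A `fastmpn_registry`.
#' @param vocab The `fastmpn_vocab` the registry was built against.
#' @param path Output path.
#' @export
write_registry <- function(registry, vocab, path) {
  tbl <- tibble::tibble(
    word_a = vocab_word(vocab, registry$pair_a),
    word_b = vocab_word(vocab, registry$pair_b),
    edge_id = seq_along(registry$pair_a),
    count = registry$count
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}
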