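#' Model configuration
#'
#' @param w Embedding length (default 300; synthetic-scale experiments in this
#'   package typically use 16–64).
#' @param mode Message aggregation: `"sparse_sum"` (default; gather–scatter
#'   weighted sum over the flat edge list), `"dense_sum"` (the same weighted
#'   sum realized as a full adjacency-matrix product; kept as the testing
#'   oracle) or `"max"` (the reference dimension-wise maximum over incoming
#'   messages).
#' @param n_layers Number of (message, update) rounds before readout
#'   (default 1).
#' @param use_eta Interpolate each node update with a per-word trainable
#'   retention coefficient squashed into (0,1) (default `FALSE`; with
#'   self-loops the self edge already carries the retained state).
#' @param activation Elementwise nonlinearity applied to the head
#'   pre-activations inside the softmax: `"identity"` (default) or `"relu"`.
#'   A rectifier there zeroes the gradient of non-positive logits, which can
#'   freeze a head at the uniform distribution, so the linear form is the
#'   default; the rectifier is retained for fidelity to the reference readout.
#' @param dropout Dropout rate on the pooled document vector during training,
#'   in `[0, 1)` (default 0).
#' @return A `fastmpn_model_config` list.
#' @export
model_config <- function(w = 300L, mode = c("sparse_sum", "dense_sum", "max"),
                         n_layers = 1L, use_eta = FALSE,
                         activation = c("identity", "relu"), dropout = 0) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  w <- as.integer(w); n_layers <- as.integer(n_layers)
  if (is.na(w) || w < 1L) stop_config("embedding length w must be >= 1")
  if (is.na(n_layers) || n_layers < 1L) stop_config("n_layers must be >= 1")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    stop_config("dropout must be in [0, 1)")
  }
  structure(
    list(w = w, mode = mode, n_layers = n_layers, use_eta = isTRUE(use_eta),
         activation = activation, dropout = as.numeric(dropout)),
    class = "fastmpn_model_config"
  )
}

#' Initialize model parameters
#'
#' Embedding rows are drawn zero-mean with scale `1/sqrt(w)`; the padding row
#' is frozen at zero. Edge weights start at `1 + N(0, 0.01)` so that the
#' initial message pass is close to an unweighted window sum. Head matrices are
#' small zero-mean Gaussians with zero biases; raw retention coefficients start
#' at 0 (squashed value 0.5).
#'
#' @param vocab A `fastmpn_vocab`.
#' @param registry A `fastmpn_registry`.
#' @param schema A `fastmpn_schema`.
#' @param config A `fastmpn_model_config`.
#' @return A `fastmpn_params` list: `embedding` (N x w, row i = word index
#'   i-1), `edge_weights` (length `e_count`, element 1 = public edge),
#'   `eta_raw` (length N or `NULL`), `heads` (per task: `V` (classes x w),
#'   `b`).
#' @export
init_params <- function(vocab, registry, schema, config) {
  stopifnot(inherits(vocab, "fastmpn_vocab"), inherits(registry, "fastmpn_registry"),
            inherits(schema, "fastmpn_schema"), inherits(config, "fastmpn_model_config"))
  n <- vocab$n; w <- config$w
  embedding <- matrix(stats::rnorm(n * w, sd = 1 / sqrt(w)), nrow = n, ncol = w)
  embedding[PAD_INDEX + 1L, ] <- 0
  edge_weights <- 1 + stats::rnorm(registry$e_count, sd = 0.01)
  eta_raw <- if (config$use_eta) numeric(n) else NULL
  heads <- lapply(schema, function(classes) {
    list(V = matrix(stats::rnorm(length(classes) * w, sd = 0.01),
                    nrow = length(classes), ncol = w),
         b = numeric(length(classes)))
  })
  structure(
    list(embedding = embedding, edge_weights = edge_weights,
         eta_raw = eta_raw, heads = heads),
    class = "fastmpn_params"
  )
}

apply_activation <- function(z, activation) {
  switch(activation, identity = z, relu = pmax(z, 0))
}

activation_grad <- function(z, activation) {
  switch(activation, identity = array(1, dim = dim(z) %||% length(z)),
         relu = (z > 0) * 1)
}

softmax_vec <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

# node-state matrix for a graph: embedding rows gathered by node word
node_states <- function(graph, params) {
  params$embedding[graph$node_words + 1L, , drop = FALSE]
}

#' Message passing over one document graph
#'
#' Three realizations of the aggregation step. `message_max()` is the
#' reference mode: each node receives, dimension-wise, the maximum of
#' `e_an * r_a` over its incoming edges. `message_dense()` is the weighted sum
#' `M'_n = sum_i e_in r_i` over all nodes, realized as a full adjacency-matrix
#' product (zero weight for non-adjacent pairs). `message_sparse()` computes
#' the identical sum by gathering edge-indexed embedding rows and weights into
#' flat arrays and scatter-summing by target node, which is the fast path; the
#' two sum modes agree up to summation-order rounding.
#'
#' @param graph A `fastmpn_graph`.
#' @param params A `fastmpn_params`.
#' @param states Optional node-state matrix (n_nodes x w) to aggregate instead
#'   of the embedding lookup — used for layers beyond the first.
#' @return An n_nodes x w message matrix.
#' @export
message_sparse <- function(graph, params, states = NULL) {
  r <- states %||% node_states(graph, params)
  contrib <- params$edge_weights[graph$edge_id + 1L] * r[graph$src, , drop = FALSE]
  scatter_sum(contrib, graph$tgt, graph$n_nodes)
}

#' @rdname message_sparse
#' @export
message_dense <- function(graph, params, states = NULL) {
  r <- states %||% node_states(graph, params)
  a <- Matrix::sparseMatrix(
    i = graph$tgt, j = graph$src,
    x = params$edge_weights[graph$edge_id + 1L],
    dims = c(graph$n_nodes, graph$n_nodes)
  )
  as.matrix(Matrix::crossprod(Matrix::t(a), r))
}

#' @rdname message_sparse
#' @export
message_max <- function(graph, params, states = NULL) {
  r <- states %||% node_states(graph, params)
  incoming <- tabulate(graph$tgt, nbins = graph$n_nodes)
  if (any(incoming == 0L)) {
    stop_structural("node ", which(incoming == 0L)[1],
                    " has no incoming edges; max aggregation is undefined")
  }
  contrib <- params$edge_weights[graph$edge_id + 1L] * r[graph$src, , drop = FALSE]
  m <- matrix(-Inf, graph$n_nodes, ncol(r))
  groups <- split(seq_along(graph$tgt), graph$tgt)
  for (g in names(groups)) {
    rows <- groups[[g]]
    m[as.integer(g), ] <- apply(contrib[rows, , drop = FALSE], 2, max)
  }
  m
}

scatter_sum <- function(values, index, n_out) {
  out <- matrix(0, n_out, ncol(values))
  rs <- rowsum(values, group = index)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Node-state update
#'
#' With retention enabled, the new state is the convex combination
#' `(1 - eta) * M + eta * r_old` with `eta = sigmoid(eta_raw)` of each node's
#' word; otherwise the message replaces the state (the self edge already
#' carries the retained information).
#'
#' @param m Message matrix (n_nodes x w).
#' @param r_old Previous node states (n_nodes x w).
#' @param eta_raw Raw per-word retention coefficients (length N) or `NULL`.
#' @param node_words 0-based word index per node (used to look up `eta_raw`).
#' @param use_eta Logical.
#' @return Updated n_nodes x w state matrix.
#' @export
node_update <- function(m, r_old, eta_raw = NULL, node_words = NULL, use_eta = FALSE) {
  if (!use_eta) return(m)
  stopifnot(!is.null(eta_raw), !is.null(node_words))
  eta <- stats::plogis(eta_raw[node_words + 1L])
  (1 - eta) * m + eta * r_old
}

#' Readout: pooled document vector to per-task class distributions
#'
#' Sums the final node states over all (non-pad) nodes — invariant to node
#' order — and maps the pooled vector through each task's linear head and a
#' softmax.
#'
#' @param states Final node-state matrix (n_nodes x w); must have >= 1 row.
#' @param params A `fastmpn_params`.
#' @param schema A `fastmpn_schema`.
#' @param config A `fastmpn_model_config` (for the activation).
#' @return A named list, one probability vector per task (entries sum to 1).
#' @export
readout <- function(states, params, schema, config) {
  if (nrow(states) == 0L) stop_structural("readout over an empty document")
  pooled <- colSums(states)
  out <- lapply(schema_tasks(schema), function(task) {
    head <- params$heads[[task]]
    z <- drop(head$V %*% pooled) + head$b
    y <- softmax_vec(apply_activation(z, config$activation))
    stats::setNames(y, schema[[task]])
  })
  stats::setNames(out, schema_tasks(schema))
}

#' Full forward pass for one document
#'
#' Applies `n_layers` rounds of (message, update) starting from the embedding
#' lookup, then the sum-pooling readout. Deterministic given parameters
#' (dropout is a training-time operation and is not applied here).
#'
#' @param graph A `fastmpn_graph`.
#' @param params A `fastmpn_params`.
#' @param schema A `fastmpn_schema`.
#' @param config A `fastmpn_model_config`.
#' @return A named list of per-task probability vectors.
#' @export
forward_document <- function(graph, params, schema, config) {
  states <- node_states(graph, params)
  msg_fun <- switch(config$mode,
                    sparse_sum = message_sparse,
                    dense_sum = message_dense,
                    max = message_max)
  for (layer in seq_len(config$n_layers)) {
    m <- msg_fun(graph, params, states = states)
    states <- node_update(m, states, params$eta_raw, graph$node_words, config$use_eta)
  }
  readout(states, params, schema, config)
}

#' Count trainable parameters
#'
#' Breaks the parameter budget into the embedding table (`N * w`), the shared
#' edge-weight table (`e_count`, including the public edge), the optional
#' retention vector, and the per-task heads (`classes * w + classes`). At
#' production scale the embedding dominates: 202,373 word types at `w = 300`
#' alone contribute 60,711,900 entries.
#'
#' @param vocab A `fastmpn_vocab`, or an integer word-type count (interpreted
#'   as N words excluding sentinels when `include_sentinels = FALSE`, or the
#'   full row count otherwise).
#' @param registry A `fastmpn_registry`, or an integer edge-table size, or
#'   `NULL` for 0.
#' @param schema A `fastmpn_schema` or `NULL`.
#' @param config A `fastmpn_model_config`.
#' @param include_sentinels Count the PAD and UNK embedding rows (default
#'   `TRUE`). Set `FALSE` to count word-type rows only — the convention under
#'   which the embedding block of a 202,373-word vocabulary at w = 300 is
#'   exactly 60,711,900.
#' @return A one-row tibble: `embedding`, `edges`, `eta`, `heads`, `total`.
#' @export
count_parameters <- function(vocab, registry = NULL, schema = NULL,
                             config = model_config(), include_sentinels = TRUE) {
  n_rows <- if (inherits(vocab, "fastmpn_vocab")) {
    if (include_sentinels) vocab$n else vocab$n - 2L
  } else {
    as.numeric(vocab) + if (include_sentinels) 2 else 0
  }
  e_count <- if (is.null(registry)) 0 else if (inherits(registry, "fastmpn_registry")) {
    registry$e_count
  } else {
    as.numeric(registry)
  }
  n_eta <- if (config$use_eta) n_rows else 0
  heads <- if (is.null(schema)) 0 else {
    sum(vapply(schema, function(cls) length(cls) * (config$w + 1), numeric(1)))
  }
  embedding <- n_rows * config$w
  tibble::tibble(
    embedding = embedding, edges = e_count, eta = n_eta, heads = heads,
    total = embedding + e_count + n_eta + heads
  )
}
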