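#' Training configuration
#'
#' @param batch_size Mini-batch size (default 256).
#' @param learning_rate Step size for adaptive moment estimation (default 1e-3).
#' @param epochs Maximum epoch count (default 30).
#' @param patience Early-stopping patience, in epochs without improvement of
#'   the validation aggregate score (default 5). `Inf` disables early stopping.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param mode `"MT"` trains all schema tasks jointly with one head per task;
#'   `"ST"` trains on a single task named by `st_task`.
#' @param st_task Task name used when `mode = "ST"`.
#' @param trainable_embedding If `FALSE`, the embedding table is frozen at its
#'   initial value and only edge weights, retention and heads are updated.
#' @param shuffle Reshuffle document order every epoch (seed-deterministic).
#' @param verbose Print one line per epoch.
#' @return A `fastmpn_train_config` list.
#' @export
train_config <- function(batch_size = 256L, learning_rate = 1e-3, epochs = 30L,
                         patience = 5L, seed = 1L,
                         mode = c("MT", "ST"), st_task = NULL,
                         trainable_embedding = TRUE, shuffle = TRUE,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) stop_config("batch_size must be >= 1")
  if (mode == "ST" && (is.null(st_task) || length(st_task) != 1L)) {
    stop_config("mode 'ST' requires exactly one st_task")
  }
  structure(
    list(batch_size = batch_size, learning_rate = learning_rate,
         epochs = as.integer(epochs), patience = patience, seed = as.integer(seed),
         mode = mode, st_task = st_task,
         trainable_embedding = isTRUE(trainable_embedding),
         shuffle = isTRUE(shuffle), verbose = isTRUE(verbose)),
    class = "fastmpn_train_config"
  )
}

#' Assemble mini-batches from an encoded corpus
#'
#' Every document appears exactly once; shuffling is seed-deterministic; the
#' final short batch is kept. Each batch carries a padded token-index matrix
#' (padded entries are the PAD index), the flattened node and edge lists used
#' by the gather–scatter message pass, and per-task label vectors with a
#' missing-label mask.
#'
#' @param encoded An encoded corpus tibble (see [encode_corpus()]).
#' @param registry A `fastmpn_registry`.
#' @param batch_size Documents per batch.
#' @param seed Shuffle seed.
#' @param shuffle Shuffle document order before slicing.
#' @param graphs Optional precomputed list of `fastmpn_graph`s (one per row of
#'   `encoded`), to avoid rebuilding them every epoch.
#' @return A list of `fastmpn_batch` objects.
#' @export
make_batches <- function(encoded, registry, batch_size, seed = 1L, shuffle = TRUE,
                         graphs = NULL) {
  stopifnot(is.data.frame(encoded), inherits(registry, "fastmpn_registry"))
  n <- nrow(encoded)
  if (n == 0L) return(list())
  if (is.null(graphs)) {
    graphs <- lapply(encoded$tokens, build_document_graph, registry = registry)
  }
  ord <- seq_len(n)
  if (shuffle) {
    ord <- withr::with_seed(as.integer(seed), sample.int(n))
  }
  starts <- seq.int(1L, n, by = batch_size)
  task_cols <- grep("^label_", names(encoded), value = TRUE)
  lapply(starts, function(s) {
    idx <- ord[seq.int(s, min(s + batch_size - 1L, n))]
    build_batch(encoded[idx, , drop = FALSE], graphs[idx], task_cols)
  })
}

build_batch <- function(rows, graphs, task_cols) {
  n_docs <- nrow(rows)
  lens <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offsets <- cumsum(c(0L, lens[-n_docs]))
  max_len <- max(lens)
  token_mat <- matrix(PAD_INDEX, n_docs, max_len)
  for (i in seq_len(n_docs)) token_mat[i, seq_len(lens[i])] <- graphs[[i]]$node_words

  node_word <- unlist(lapply(graphs, function(g) g$node_words), use.names = FALSE)
  node_doc <- rep.int(seq_len(n_docs), lens)
  src <- unlist(lapply(seq_len(n_docs), function(i) graphs[[i]]$src + offsets[i]),
                use.names = FALSE)
  tgt <- unlist(lapply(seq_len(n_docs), function(i) graphs[[i]]$tgt + offsets[i]),
                use.names = FALSE)
  edge_id <- unlist(lapply(graphs, function(g) g$edge_id), use.names = FALSE)

  labels <- lapply(task_cols, function(col) rows[[col]])
  names(labels) <- sub("^label_", "", task_cols)
  structure(
    list(doc_id = rows$doc_id, n_docs = n_docs, token_mat = token_mat,
         node_word = node_word, node_doc = node_doc, n_nodes = length(node_word),
         src = src, tgt = tgt, edge_id = edge_id, labels = labels),
    class = "fastmpn_batch"
  )
}

#' Masked multi-task cross-entropy loss
#'
#' Mean over documents of the sum, over tasks with an observed label, of the
#' cross-entropy between the predicted distribution and the true class.
#' Masked (missing) labels contribute exactly zero; task weights are equal.
#'
#' @param predictions A list, one element per document, each a named list of
#'   per-task probability vectors (as returned by [forward_document()]).
#' @param labels A named list of per-task integer class-index vectors (1-based,
#'   `NA` = masked), each of length `length(predictions)`.
#' @return Scalar loss.
#' @export
multitask_loss <- function(predictions, labels) {
  n_docs <- length(predictions)
  if (n_docs == 0L) stop_config("no documents")
  if (all(vapply(labels, function(l) all(is.na(l)), logical(1)))) {
    stop_config("no unmasked labels in batch")
  }
  total <- 0
  for (task in names(labels)) {
    lab <- labels[[task]]
    for (i in seq_len(n_docs)) {
      if (!is.na(lab[i])) {
        p <- predictions[[i]][[task]][lab[i]]
        total <- total - log(max(p, .Machine$double.xmin))
      }
    }
  }
  total / n_docs
}

# ---------------------------------------------------------------------------
# batched forward/backward with hand-derived gradients

active_tasks <- function(schema, tconfig) {
  if (tconfig$mode == "ST") {
    if (!tconfig$st_task %in% schema_tasks(schema)) {
      stop_config("unknown ST task '", tconfig$st_task, "'")
    }
    tconfig$st_task
  } else {
    schema_tasks(schema)
  }
}

batch_forward <- function(params, batch, schema, config, tasks = schema_tasks(schema),
                          dropout_mask = NULL) {
  states <- params$embedding[batch$node_word + 1L, , drop = FALSE]
  layer_in <- vector("list", config$n_layers)
  layer_msg <- vector("list", config$n_layers)
  layer_amax <- vector("list", config$n_layers)
  e <- params$edge_weights[batch$edge_id + 1L]

  for (l in seq_len(config$n_layers)) {
    layer_in[[l]] <- states
    if (config$mode == "max") {
      mm <- batch_message_max(states, e, batch$src, batch$tgt, batch$n_nodes)
      m <- mm$m
      layer_amax[[l]] <- mm$amax
    } else {
      contrib <- e * states[batch$src, , drop = FALSE]
      m <- scatter_sum(contrib, batch$tgt, batch$n_nodes)
    }
    layer_msg[[l]] <- m
    states <- node_update(m, states, params$eta_raw, batch$node_word, config$use_eta)
  }

  pooled <- scatter_sum(states, batch$node_doc, batch$n_docs)
  pooled_used <- if (is.null(dropout_mask)) pooled else pooled * dropout_mask

  heads <- list()
  loss <- 0
  n_labeled <- 0L
  for (task in tasks) {
    hd <- params$heads[[task]]
    z <- pooled_used %*% t(hd$V) + matrix(hd$b, batch$n_docs, length(hd$b), byrow = TRUE)
    a <- apply_activation(z, config$activation)
    amax <- apply(a, 1, max)
    expa <- exp(a - amax)
    y <- expa / rowSums(expa)
    lab <- batch$labels[[task]]
    obs <- which(!is.na(lab))
    if (length(obs) > 0L) {
      p <- y[cbind(obs, lab[obs])]
      loss <- loss + sum(-log(pmax(p, .Machine$double.xmin)))
      n_labeled <- n_labeled + length(obs)
    }
    heads[[task]] <- list(z = z, y = y)
  }
  if (n_labeled == 0L) stop_config("no unmasked labels in batch")
  loss <- loss / batch$n_docs
  list(states = states, layer_in = layer_in, layer_msg = layer_msg,
       layer_amax = layer_amax, pooled = pooled, pooled_used = pooled_used,
       heads = heads, loss = loss, edge_e = e, tasks = tasks,
       dropout_mask = dropout_mask)
}

# reference max aggregation over a flat edge list, recording argmax edges
batch_message_max <- function(states, e, src, tgt, n_nodes) {
  w <- ncol(states)
  contrib <- e * states[src, , drop = FALSE]
  incoming <- tabulate(tgt, nbins = n_nodes)
  if (any(incoming == 0L)) {
    stop_structural("node with no incoming edges in max aggregation")
  }
  m <- matrix(-Inf, n_nodes, w)
  amax <- matrix(NA_integer_, n_nodes, w)
  groups <- split(seq_along(tgt), tgt)
  for (g in names(groups)) {
    rows <- groups[[g]]
    block <- contrib[rows, , drop = FALSE]
    pick <- max.col(t(block), ties.method = "first")
    n_i <- as.integer(g)
    m[n_i, ] <- block[cbind(pick, seq_len(w))]
    amax[n_i, ] <- rows[pick]
  }
  list(m = m, amax = amax)
}

batch_backward <- function(params, batch, schema, config, fwd) {
  n_docs <- batch$n_docs
  w <- ncol(params$embedding)
  grads <- list(
    embedding = NULL,
    edge_weights = numeric(length(params$edge_weights)),
    eta_raw = if (config$use_eta) numeric(length(params$eta_raw)) else NULL,
    heads = list()
  )
  d_pooled_used <- matrix(0, n_docs, w)
  for (task in fwd$tasks) {
    hd <- params$heads[[task]]
    y <- fwd$heads[[task]]$y
    z <- fwd$heads[[task]]$z
    lab <- batch$labels[[task]]
    obs <- !is.na(lab)
    da <- y
    da[cbind(which(obs), lab[obs])] <- da[cbind(which(obs), lab[obs])] - 1
    da[!obs, ] <- 0
    da <- da / n_docs
    dz <- da * activation_grad(z, config$activation)
    grads$heads[[task]] <- list(V = t(dz) %*% fwd$pooled_used, b = colSums(dz))
    d_pooled_used <- d_pooled_used + dz %*% hd$V
  }
  d_pooled <- if (is.null(fwd$dropout_mask)) d_pooled_used else d_pooled_used * fwd$dropout_mask
  d_states <- d_pooled[batch$node_doc, , drop = FALSE]

  e <- fwd$edge_e
  d_edge_flat <- numeric(length(e))
  for (l in rev(seq_len(config$n_layers))) {
    states_in <- fwd$layer_in[[l]]
    m <- fwd$layer_msg[[l]]
    if (config$use_eta) {
      eta <- stats::plogis(params$eta_raw[batch$node_word + 1L])
      d_m <- (1 - eta) * d_states
      d_in_partial <- eta * d_states
      d_eta <- rowSums((states_in - m) * d_states) * eta * (1 - eta)
      agg <- rowsum(d_eta, group = batch$node_word)
      grads$eta_raw[as.integer(rownames(agg)) + 1L] <-
        grads$eta_raw[as.integer(rownames(agg)) + 1L] + agg[, 1]
    } else {
      d_m <- d_states
      d_in_partial <- 0
    }
    if (config$mode == "max") {
      amax <- fwd$layer_amax[[l]]
      d_in <- matrix(0, batch$n_nodes, w)
      for (k in seq_len(w)) {
        edges_k <- amax[, k]
        contrib <- d_m[, k]
        agg_e <- rowsum(contrib * states_in[cbind(batch$src[edges_k], k)], group = edges_k)
        d_edge_flat[as.integer(rownames(agg_e))] <-
          d_edge_flat[as.integer(rownames(agg_e))] + agg_e[, 1]
        agg_s <- rowsum(contrib * e[edges_k], group = batch$src[edges_k])
        d_in[as.integer(rownames(agg_s)), k] <-
          d_in[as.integer(rownames(agg_s)), k] + agg_s[, 1]
      }
    } else {
      d_m_tgt <- d_m[batch$tgt, , drop = FALSE]
      s_src <- states_in[batch$src, , drop = FALSE]
      d_edge_flat <- d_edge_flat + rowSums(d_m_tgt * s_src)
      d_in <- scatter_sum(e * d_m_tgt, batch$src, batch$n_nodes)
    }
    d_states <- d_in + d_in_partial
  }

  agg <- rowsum(d_edge_flat, group = batch$edge_id)
  grads$edge_weights[as.integer(rownames(agg)) + 1L] <- agg[, 1]

  emb_agg <- rowsum(d_states, group = batch$node_word)
  g_emb <- matrix(0, nrow(params$embedding), w)
  g_emb[as.integer(rownames(emb_agg)) + 1L, ] <- emb_agg
  g_emb[PAD_INDEX + 1L, ] <- 0      # padding row is frozen
  grads$embedding <- g_emb
  grads
}

# ---------------------------------------------------------------------------
# adaptive moment estimation

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(
    t = 0L,
    m = list(embedding = zero_like(params$embedding),
             edge_weights = zero_like(params$edge_weights),
             eta_raw = if (is.null(params$eta_raw)) NULL else zero_like(params$eta_raw),
             heads = lapply(params$heads, function(h) list(V = zero_like(h$V), b = zero_like(h$b)))),
    v = list(embedding = zero_like(params$embedding),
             edge_weights = zero_like(params$edge_weights),
             eta_raw = if (is.null(params$eta_raw)) NULL else zero_like(params$eta_raw),
             heads = lapply(params$heads, function(h) list(V = zero_like(h$V), b = zero_like(h$b))))
  )
}

adam_step_one <- function(x, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_update <- function(params, grads, state, lr, tasks, trainable_embedding = TRUE,
                        use_eta = FALSE) {
  state$t <- state$t + 1L
  t <- state$t
  if (trainable_embedding) {
    up <- adam_step_one(params$embedding, grads$embedding,
                        state$m$embedding, state$v$embedding, lr, t)
    params$embedding <- up$x
    params$embedding[PAD_INDEX + 1L, ] <- 0
    state$m$embedding <- up$m; state$v$embedding <- up$v
  }
  up <- adam_step_one(params$edge_weights, grads$edge_weights,
                      state$m$edge_weights, state$v$edge_weights, lr, t)
  params$edge_weights <- up$x
  state$m$edge_weights <- up$m; state$v$edge_weights <- up$v
  if (use_eta) {
    up <- adam_step_one(params$eta_raw, grads$eta_raw,
                        state$m$eta_raw, state$v$eta_raw, lr, t)
    params$eta_raw <- up$x
    state$m$eta_raw <- up$m; state$v$eta_raw <- up$v
  }
  for (task in tasks) {
    up <- adam_step_one(params$heads[[task]]$V, grads$heads[[task]]$V,
                        state$m$heads[[task]]$V, state$v$heads[[task]]$V, lr, t)
    params$heads[[task]]$V <- up$x
    state$m$heads[[task]]$V <- up$m; state$v$heads[[task]]$V <- up$v
    up <- adam_step_one(params$heads[[task]]$b, grads$heads[[task]]$b,
                        state$m$heads[[task]]$b, state$v$heads[[task]]$b, lr, t)
    params$heads[[task]]$b <- up$x
    state$m$heads[[task]]$b <- up$m; state$v$heads[[task]]$b <- up$v
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------

#' Fit a fast message passing network
#'
#' Runs the full pipeline on a raw corpus tibble: tokenization, vocabulary and
#' edge-registry construction (from the training split only, so validation and
#' test words fall back to the unknown sentinel and unseen pairs to the public
#' edge), parameter initialization, and mini-batched multi-task training of the
#' summed cross-entropy by adaptive moment estimation. The whole loop is
#' seed-deterministic: the same seed gives a bit-identical loss trajectory.
#'
#' @param corpus Training corpus tibble (`doc_id`, `text`, one label column per
#'   task; missing labels are masked out of the loss).
#' @param schema A `fastmpn_schema`.
#' @param validation Optional validation corpus tibble. Per-epoch micro/macro
#'   F1 and the aggregate score are computed on it; early stopping and
#'   best-checkpoint selection use the aggregate.
#' @param gow A `fastmpn_gow_config`.
#' @param model A `fastmpn_model_config`.
#' @param train A `fastmpn_train_config`.
#' @param min_count,max_len Vocabulary and encoding controls (see
#'   [build_vocabulary()], [encode_corpus()]).
#' @return A `fastmpn_model`: list with `params`, `vocab`, `registry`,
#'   `schema`, `model_config`, `train_config`, `log` (one row per epoch:
#'   `epoch`, `train_loss`, `micro_<task>`, `macro_<task>`, `aggregate`) and
#'   `best_epoch`.
#' @export
fastmpn_fit <- function(corpus, schema, validation = NULL,
                        gow = gow_config(), model = model_config(),
                        train = train_config(), min_count = 1L, max_len = 1500L) {
  stopifnot(is.data.frame(corpus), inherits(schema, "fastmpn_schema"))
  vocab <- build_vocabulary(corpus, min_count = min_count)
  encoded <- encode_corpus(corpus, vocab, schema, max_len = max_len)
  registry <- build_edge_registry(encoded, vocab, gow)
  val_encoded <- if (!is.null(validation)) {
    encode_corpus(validation, vocab, schema, max_len = max_len)
  }
  train_model(encoded, registry, vocab, schema, model, train,
              val_encoded = val_encoded)
}

#' @rdname fastmpn_fit
#' @param encoded,registry,vocab Pre-built encoded corpus, edge registry and
#'   vocabulary (the lower-level entry point used by [fastmpn_fit()]).
#' @param val_encoded Optional encoded validation corpus.
#' @param resume_from Optional `fastmpn_model` whose parameters and epoch
#'   numbering are continued.
#' @export
train_model <- function(encoded, registry, vocab, schema,
                        model = model_config(), train = train_config(),
                        val_encoded = NULL, resume_from = NULL) {
  tconfig <- train; mconfig <- model
  stopifnot(inherits(mconfig, "fastmpn_model_config"),
            inherits(tconfig, "fastmpn_train_config"))
  tasks <- active_tasks(schema, tconfig)

  graphs <- lapply(encoded$tokens, build_document_graph, registry = registry)
  val_graphs <- if (!is.null(val_encoded)) {
    lapply(val_encoded$tokens, build_document_graph, registry = registry)
  }

  epoch_offset <- 0L
  log_rows <- list()
  withr::with_seed(tconfig$seed, {
    if (is.null(resume_from)) {
      params <- init_params(vocab, registry, schema, mconfig)
    } else {
      params <- resume_from$params
      epoch_offset <- if (nrow(resume_from$log) > 0L) max(resume_from$log$epoch) else 0L
      log_rows <- list(resume_from$log)
    }
    opt <- adam_init(params)
    best <- list(score = -Inf, params = params, epoch = epoch_offset)
    stall <- 0L

    for (epoch in seq_len(tconfig$epochs)) {
      batches <- make_batches(encoded, registry, tconfig$batch_size,
                              seed = tconfig$seed + epoch, shuffle = tconfig$shuffle,
                              graphs = graphs)
      epoch_loss <- 0; epoch_docs <- 0L
      for (b in batches) {
        mask <- NULL
        if (mconfig$dropout > 0) {
          keep <- stats::runif(b$n_docs * mconfig$w) >= mconfig$dropout
          mask <- matrix(keep / (1 - mconfig$dropout), b$n_docs, mconfig$w)
        }
        fwd <- batch_forward(params, b, schema, mconfig, tasks = tasks,
                             dropout_mask = mask)
        if (!is.finite(fwd$loss)) {
          stop(errorCondition(
            paste0("training diverged at epoch ", epoch + epoch_offset,
                   " (non-finite loss)"),
            class = c("fastmpn_divergence_error", "fastmpn_error")
          ))
        }
        grads <- batch_backward(params, b, schema, mconfig, fwd)
        up <- adam_update(params, grads, opt, tconfig$learning_rate, tasks,
                          trainable_embedding = tconfig$trainable_embedding,
                          use_eta = mconfig$use_eta)
        params <- up$params; opt <- up$state
        epoch_loss <- epoch_loss + fwd$loss * b$n_docs
        epoch_docs <- epoch_docs + b$n_docs
      }
      row <- tibble::tibble(epoch = epoch + epoch_offset,
                            train_loss = epoch_loss / epoch_docs)
      if (!is.null(val_encoded)) {
        scores <- score_encoded(params, val_encoded, val_graphs, schema, mconfig, tasks,
                                batch_size = tconfig$batch_size)
        for (task in tasks) {
          row[[paste0("micro_", task)]] <- scores$micro[[task]]
          row[[paste0("macro_", task)]] <- scores$macro[[task]]
        }
        row$aggregate <- scores$aggregate
        if (scores$aggregate > best$score) {
          best <- list(score = scores$aggregate, params = params,
                       epoch = epoch + epoch_offset)
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      log_rows[[length(log_rows) + 1L]] <- row
      if (tconfig$verbose) {
        msg <- sprintf("epoch %d  loss %.4f", epoch + epoch_offset, row$train_loss)
        if (!is.null(row$aggregate)) msg <- sprintf("%s  val aggregate %.4f", msg, row$aggregate)
        message(msg)
      }
      if (!is.null(val_encoded) && stall >= tconfig$patience) break
    }
    if (is.null(val_encoded)) best <- list(score = NA_real_, params = params,
                                           epoch = epoch_offset + tconfig$epochs)
  })

  structure(
    list(params = best$params, vocab = vocab, registry = registry, schema = schema,
         model_config = mconfig, train_config = tconfig,
         log = dplyr::bind_rows(log_rows), best_epoch = best$epoch),
    class = "fastmpn_model"
  )
}

# argmax predictions + per-task micro/macro on an encoded corpus
score_encoded <- function(params, encoded, graphs, schema, mconfig, tasks,
                          batch_size = 256L) {
  pred <- predict_encoded(params, encoded, graphs, schema, mconfig,
                          batch_size = batch_size)
  micro <- list(); macro <- list()
  for (task in tasks) {
    truth <- encoded[[paste0("label_", task)]]
    obs <- !is.na(truth)
    micro[[task]] <- micro_f1(truth[obs], pred$class_index[[task]][obs])
    macro[[task]] <- macro_f1(truth[obs], pred$class_index[[task]][obs])
  }
  list(micro = micro, macro = macro,
       aggregate = aggregate_scores(c(unlist(micro), unlist(macro))))
}

# batched inference: per-task argmax index and its probability
predict_encoded <- function(params, encoded, graphs, schema, mconfig,
                            batch_size = 256L) {
  batches <- make_batches(encoded, registry = structure(list(config = gow_config()),
                                                        class = "fastmpn_registry"),
                          batch_size = batch_size, shuffle = FALSE, graphs = graphs)
  tasks <- schema_tasks(schema)
  class_index <- stats::setNames(rep(list(integer(0)), length(tasks)), tasks)
  prob <- stats::setNames(rep(list(numeric(0)), length(tasks)), tasks)
  probs_full <- stats::setNames(rep(list(list()), length(tasks)), tasks)
  for (b in batches) {
    fwd_labels <- b$labels
    b$labels <- stats::setNames(list(rep(1L, b$n_docs)), "..dummy..")
    states <- params$embedding[b$node_word + 1L, , drop = FALSE]
    e <- params$edge_weights[b$edge_id + 1L]
    for (l in seq_len(mconfig$n_layers)) {
      if (mconfig$mode == "max") {
        states_new <- batch_message_max(states, e, b$src, b$tgt, b$n_nodes)$m
      } else {
        contrib <- e * states[b$src, , drop = FALSE]
        states_new <- scatter_sum(contrib, b$tgt, b$n_nodes)
      }
      states <- node_update(states_new, states, params$eta_raw, b$node_word,
                            mconfig$use_eta)
    }
    pooled <- scatter_sum(states, b$node_doc, b$n_docs)
    for (task in tasks) {
      hd <- params$heads[[task]]
      z <- pooled %*% t(hd$V) + matrix(hd$b, b$n_docs, length(hd$b), byrow = TRUE)
      a <- apply_activation(z, mconfig$activation)
      expa <- exp(a - apply(a, 1, max))
      y <- expa / rowSums(expa)
      ci <- max.col(y, ties.method = "first")
      class_index[[task]] <- c(class_index[[task]], ci)
      prob[[task]] <- c(prob[[task]], y[cbind(seq_len(b$n_docs), ci)])
      probs_full[[task]][[length(probs_full[[task]]) + 1L]] <- y
    }
  }
  list(class_index = class_index, prob = prob,
       probs = lapply(probs_full, function(lst) do.call(rbind, lst)))
}

#' @export
print.fastmpn_model <- function(x, ...) {
  counts <- count_parameters(x$vocab, x$registry, x$schema, x$model_config,
                             include_sentinels = TRUE)
  cat("<fastmpn_model>\n",
      "  vocabulary: N = ", x$vocab$n, "\n",
      "  edges: ", x$registry$e_count, " (incl. public)\n",
      "  tasks: ", paste(schema_tasks(x$schema), collapse = ", "), "\n",
      "  mode: ", x$model_config$mode, ", w = ", x$model_config$w, "\n",
      "  trainable parameters: ", format(counts$total, big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

#' Predict classes for new documents
#'
#' Runs the deterministic forward pass on a raw corpus tibble. Words never
#' seen in training map to the unknown sentinel and unseen word pairs to the
#' public edge, so inference on new documents always succeeds.
#'
#' @param object A `fastmpn_model`.
#' @param newdata A corpus tibble with `doc_id` and `text` (label columns are
#'   ignored).
#' @param ... Unused.
#' @return A tibble with `doc_id`, one column per task holding the argmax
#'   class string, and one `<task>_prob` column holding its probability.
#' @export
predict.fastmpn_model <- function(object, newdata, ...) {
  encoded <- encode_corpus(newdata, object$vocab, object$schema)
  graphs <- lapply(encoded$tokens, build_document_graph, registry = object$registry)
  pred <- predict_encoded(object$params, encoded, graphs, object$schema,
                          object$model_config,
                          batch_size = object$train_config$batch_size)
  out <- tibble::tibble(doc_id = encoded$doc_id)
  for (task in schema_tasks(object$schema)) {
    out[[task]] <- object$schema[[task]][pred$class_index[[task]]]
    out[[paste0(task, "_prob")]] <- pred$prob[[task]]
  }
  out
}

#' Export a training log as JSON Lines
#'
#' One record per epoch with the train loss, per-task validation scores and
#' the aggregate.
#'
#' @param model A `fastmpn_model`.
#' @param path Output path.
#' @export
write_training_log <- function(model, path) {
  stopifnot(inherits(model, "fastmpn_model"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(model$log))) {
    writeLines(jsonlite::toJSON(as.list(model$log[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
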