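#' Tokenize free text
#'
#' Lowercases the input and extracts maximal runs of alphanumeric characters;
#' every other character is a separator and is dropped. This deliberately
#' splits on hyphens and punctuation so that variants such as `"grade (g1-3): 3"`
#' and `"grade 3"` share their informative tokens, and keeps digits because
#' grade labels are numeric.
#'
#' @param text Character vector of raw document strings.
#' @return A list of character vectors, one per input string (a single
#'   character vector if `text` has length 1 and `simplify` is `TRUE`).
#' @param simplify If `TRUE` (default) and `text` has length 1, return the
#'   token vector itself rather than a one-element list.
#' @export
#' @examples
#' tokenize("Histologic grade (G1-3): 3")
tokenize <- function(text, simplify = TRUE) {
  stopifnot(is.character(text))
  toks <- stringr::str_extract_all(stringr::str_to_lower(text), "[[:alnum:]]+")
  if (simplify && length(toks) == 1L) toks[[1]] else toks
}

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
PAD_INDEX <- 0L
UNK_INDEX <- 1L

#' Build a vocabulary from a corpus
#'
#' Tokenizes every document and registers each token whose corpus frequency is
#' at least `min_count`. Indices are 0-based: index 0 is the padding sentinel,
#' index 1 the unknown-word sentinel, and real words occupy 2..N-1 ordered by
#' descending corpus frequency with lexicographic tie-break, so the mapping is
#' deterministic for a given corpus.
#'
#' @param corpus A corpus tibble with at least a `text` column (see
#'   [read_corpus()]).
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (default 1: keep all words).
#' @return A `fastmpn_vocab` object with fields `word` (character vector in
#'   index order, sentinels first), `freq` (corpus frequencies; 0 for
#'   sentinels) and `n` (total size N including sentinels).
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  stopifnot(is.data.frame(corpus), "text" %in% names(corpus))
  if (nrow(corpus) == 0L) {
    stop_config("cannot build a vocabulary from an empty corpus")
  }
  if (min_count < 1L) {
    stop_config("min_count must be >= 1")
  }
  tokens <- unlist(tokenize(corpus$text, simplify = FALSE), use.names = FALSE)
  counts <- table(tokens)
  counts <- counts[counts >= min_count]
  words <- names(counts)
  freqs <- as.integer(counts)
  ord <- order(-freqs, words, method = "radix")
  new_vocab(
    word = c(PAD_TOKEN, UNK_TOKEN, words[ord]),
    freq = c(0L, 0L, freqs[ord])
  )
}

new_vocab <- function(word, freq) {
  stopifnot(length(word) == length(freq), word[1] == PAD_TOKEN, word[2] == UNK_TOKEN)
  structure(
    list(word = word, freq = as.integer(freq), n = length(word)),
    class = "fastmpn_vocab"
  )
}

#' @export
print.fastmpn_vocab <- function(x, ...) {
  cat("<fastmpn_vocab> N = ", x$n, " (", x$n - 2L, " words + 2 sentinels)\n", sep = "")
  invisible(x)
}

#' Map words to vocabulary indices and back
#'
#' `vocab_index()` returns 0-based indices with out-of-vocabulary words mapped
#' to the unknown sentinel (index 1); `vocab_word()` inverts in-range indices.
#'
#' @param vocab A `fastmpn_vocab`.
#' @param words Character vector.
#' @return Integer vector of 0-based indices.
#' @export
vocab_index <- function(vocab, words) {
  idx <- match(words, vocab$word)
  idx[is.na(idx)] <- UNK_INDEX + 1L
  as.integer(idx - 1L)
}

#' @rdname vocab_index
#' @param index Integer vector of 0-based indices, all `< vocab$n`.
#' @export
vocab_word <- function(vocab, index) {
  stopifnot(all(index >= 0L), all(index < vocab$n))
  vocab$word[index + 1L]
}

#' Read and write vocabularies as TSV
#'
#' Columns `index`, `word`, `corpus_frequency`, rows in index order (sentinels
#' first). The writer and reader are exact inverses.
#'
#' @param vocab A `fastmpn_vocab`.
#' @param path File path.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "fastmpn_vocab"))
  tbl <- tibble::tibble(
    index = seq_len(vocab$n) - 1L,
    word = vocab$word,
    corpus_frequency = vocab$freq
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  if (!file.exists(path)) stop_io("vocabulary file not found: ", path)
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    index = readr::col_integer(),
    word = readr::col_character(),
    corpus_frequency = readr::col_integer()
  ), progress = FALSE)
  if (!identical(tbl$index, seq_len(nrow(tbl)) - 1L)) {
    stop_parse("vocabulary TSV indices must be dense and 0-based: ", path)
  }
  new_vocab(tbl$word, tbl$corpus_frequency)
}

#' Encode a corpus as token-index sequences
#'
#' Tokenizes each document, maps tokens to 0-based vocabulary indices (unknown
#' words to the unknown sentinel), truncates to `max_len` tokens, and maps each
#' task's class string to its 1-based position in the schema's class registry
#' (`NA` when the label is missing). Documents that tokenize to zero tokens are
#' rejected: an empty graph has no readout.
#'
#' @param corpus A corpus tibble with `doc_id`, `text`, and one column per
#'   schema task.
#' @param vocab A `fastmpn_vocab`.
#' @param schema A `fastmpn_schema`.
#' @param max_len Maximum encoded length (default 1500 tokens).
#' @param truncate `"head"` (default) keeps the earliest tokens — diagnosis
#'   fields typically lead a pathology report — `"tail"` keeps the latest.
#' @return A tibble with `doc_id`, `tokens` (list-column of 0-based integer
#'   vectors), `n_tokens`, and one integer class-index column per task named
#'   `label_<task>`.
#' @export
encode_corpus <- function(corpus, vocab, schema, max_len = 1500L, truncate = c("head", "tail")) {
  stopifnot(is.data.frame(corpus), inherits(vocab, "fastmpn_vocab"),
            inherits(schema, "fastmpn_schema"))
  truncate <- match.arg(truncate)
  if (max_len < 1L) stop_config("max_len must be >= 1")

  toks <- tokenize(corpus$text, simplify = FALSE)
  n_tok <- lengths(toks)
  if (any(n_tok == 0L)) {
    bad <- corpus$doc_id[which(n_tok == 0L)[1]]
    cond <- errorCondition(
      paste0("document '", bad, "' tokenizes to zero tokens"),
      doc_id = bad,
      class = c("fastmpn_empty_document_error", "fastmpn_error")
    )
    stop(cond)
  }
  encoded <- lapply(toks, function(tk) {
    if (length(tk) > max_len) {
      tk <- if (truncate == "head") tk[seq_len(max_len)] else tk[seq.int(length(tk) - max_len + 1L, length(tk))]
    }
    vocab_index(vocab, tk)
  })

  out <- tibble::tibble(
    doc_id = corpus$doc_id,
    tokens = encoded,
    n_tokens = lengths(encoded)
  )
  for (task in schema_tasks(schema)) {
    if (!task %in% names(corpus)) {
      out[[paste0("label_", task)]] <- NA_integer_
      next
    }
    lab <- as.character(corpus[[task]])
    idx <- match(lab, schema[[task]])
    bad <- !is.na(lab) & is.na(idx)
    if (any(bad)) {
      stop_schema("task '", task, "': label '", lab[which(bad)[1]],
                  "' is not in the schema")
    }
    out[[paste0("label_", task)]] <- as.integer(idx)
  }
  out
}
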