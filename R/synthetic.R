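# Template families for the synthetic pathology-report generator.
# Each task maps class -> list of token-sequence forms (first form = canonical).
# Class value tokens are kept disjoint from field names, parenthetical hints,
# filler sentences and noise tokens, so a rule-based matcher can always
# recover the label when noise is off — the classification task is solvable
# by construction.
synthetic_templates <- function() {
  list(
    site = list(
      field = c("primary", "site"),
      hints = list(c("topography")),
      classes = list(
        lung     = list(c("lung"), c("pulmonary")),
        breast   = list(c("breast"), c("mammary")),
        colon    = list(c("colon"), c("colonic")),
        prostate = list(c("prostate"), c("prostatic")),
        skin     = list(c("skin"), c("cutaneous")),
        kidney   = list(c("kidney"), c("renal"))
      )
    ),
    subsite = list(
      field = c("subsite"),
      hints = list(c("location")),
      classes = list(
        "upper lobe"        = list(c("upper", "lobe"), c("lobe", "superior")),
        "lower lobe"        = list(c("lower", "lobe"), c("lobe", "inferior")),
        "outer quadrant"    = list(c("outer", "quadrant")),
        "inner quadrant"    = list(c("inner", "quadrant")),
        "ascending segment" = list(c("ascending", "segment")),
        "sigmoid segment"   = list(c("sigmoid", "segment")),
        "apex region"       = list(c("apex", "region")),
        "peripheral region" = list(c("peripheral", "region")),
        "trunk surface"     = list(c("trunk", "surface")),
        "limb surface"      = list(c("limb", "surface")),
        "cortex"            = list(c("cortex")),
        "pelvis"            = list(c("pelvis"))
      )
    ),
    laterality = list(
      field = c("laterality"),
      hints = list(c("side")),
      classes = list(
        left      = list(c("left"), c("lt")),
        right     = list(c("right"), c("rt")),
        bilateral = list(c("bilateral")),
        midline   = list(c("midline"), c("median"))
      )
    ),
    histology = list(
      field = c("histologic", "type"),
      hints = list(c("morphology")),
      classes = list(
        adenocarcinoma = list(c("adenocarcinoma")),
        melanoma       = list(c("melanoma")),
        lymphoma       = list(c("lymphoma")),
        sarcoma        = list(c("sarcoma")),
        carcinoid      = list(c("carcinoid")),
        fibroma        = list(c("fibroma")),
        lipoma         = list(c("lipoma")),
        glioma         = list(c("glioma")),
        mesothelioma   = list(c("mesothelioma")),
        osteosarcoma   = list(c("osteosarcoma"))
      )
    ),
    behavior = list(
      field = c("behavior"),
      hints = list(c("code")),
      classes = list(
        benign     = list(c("benign"), c("indolent")),
        borderline = list(c("borderline"), c("uncertain")),
        malignant  = list(c("malignant"), c("invasive"))
      )
    ),
    grade = list(
      field = c("histologic", "grade"),
      hints = list(c("mbr"), c("nottingham"), c("fuhrman")),
      classes = list(
        "1" = list(c("1"), c("g1"), c("i"), c("well", "differentiated")),
        "2" = list(c("2"), c("g2"), c("ii"), c("moderately", "differentiated")),
        "3" = list(c("3"), c("g3"), c("iii"), c("poorly", "differentiated")),
        "4" = list(c("4"), c("g4"), c("iv"), c("undifferentiated")),
        "9" = list(c("9"), c("gx"), c("indeterminate"))
      )
    )
  )
}

synthetic_fillers <- function() {
  c("the specimen was received fresh and sectioned",
    "microscopic examination was performed on all blocks",
    "immunostains were reviewed by the attending pathologist",
    "clinical correlation is recommended",
    "margins appear free of tumor",
    "representative sections are submitted for review",
    "the findings were discussed at the weekly conference",
    "additional levels were examined without further yield")
}

#' Synthetic corpus generator configuration
#'
#' Controls a fully synthetic pathology-report-like corpus: short
#' semi-structured field phrases (one per task), independent variation
#' operators modeled on real registry free text — word inversion
#' ("poorly differentiated" / "differentiated poorly"), parenthetical insertion
#' ("grade 3" / "grade (mbr): 3"), synonym substitution ("3" / "g3" / "iii" /
#' "poorly differentiated") — filler sentences, optional noise tokens, and a
#' power-law class prior producing severe class imbalance. Labels are a
#' deterministic function of the rendered field phrases whenever
#' `noise_rate = 0`.
#'
#' @param n_docs Number of documents (default 5000).
#' @param seed Integer seed; the generator is fully seed-deterministic.
#' @param n_classes Named integer vector of per-task class counts. Defaults to
#'   site 6, subsite 12 (two nested under each site), laterality 4,
#'   histology 10, behavior 3, grade 5; each count may be lowered (class lists
#'   are truncated; subsite count must stay twice the site count).
#' @param imbalance Exponent of the power-law class prior `p(k) ~ k^-imbalance`
#'   (default 1.5; 0 gives balanced classes).
#' @param p_invert,p_parenthetical,p_synonym,p_omit Per-field probabilities of
#'   word inversion, parenthetical insertion, non-canonical synonym form, and
#'   field omission (omission also drops the label, exercising the loss mask).
#'   Defaults 0.3 / 0.3 / 0.5 / 0.05.
#' @param noise_rate Per-position probability of inserting an uninformative
#'   noise token (default 0).
#' @param filler_range Integer range (length 2) of filler sentences per
#'   document (default `c(1, 3)`).
#' @return A `fastmpn_generator_config` list.
#' @export
generator_config <- function(n_docs = 5000L, seed = 1L,
                             n_classes = c(site = 6L, subsite = 12L, laterality = 4L,
                                           histology = 10L, behavior = 3L, grade = 5L),
                             imbalance = 1.5,
                             p_invert = 0.3, p_parenthetical = 0.3,
                             p_synonym = 0.5, p_omit = 0.05,
                             noise_rate = 0, filler_range = c(1L, 3L)) {
  probs <- c(p_invert = p_invert, p_parenthetical = p_parenthetical,
             p_synonym = p_synonym, p_omit = p_omit, noise_rate = noise_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_config("variation probabilities and noise_rate must lie in [0, 1]")
  }
  tmpl <- synthetic_templates()
  defaults <- vapply(tmpl, function(t) length(t$classes), integer(1))
  counts <- defaults
  counts[names(n_classes)] <- as.integer(n_classes)
  if (any(counts < 2L)) stop_config("every task needs at least 2 classes")
  if (any(counts > defaults)) {
    stop_config("requested class counts exceed the template pools (",
                paste(names(defaults), defaults, sep = "=", collapse = ", "), ")")
  }
  if (counts[["subsite"]] != 2L * counts[["site"]]) {
    stop_config("subsite class count must be twice the site count (2 subsites nested per site)")
  }
  if (length(filler_range) != 2L || any(filler_range < 0L) ||
      filler_range[1] > filler_range[2]) {
    stop_config("filler_range must be c(lo, hi) with 0 <= lo <= hi")
  }
  structure(
    list(n_docs = as.integer(n_docs), seed = as.integer(seed),
         n_classes = counts, imbalance = as.numeric(imbalance),
         p_invert = p_invert, p_parenthetical = p_parenthetical,
         p_synonym = p_synonym, p_omit = p_omit,
         noise_rate = noise_rate, filler_range = as.integer(filler_range)),
    class = "fastmpn_generator_config"
  )
}

# templates truncated to the configured class counts
active_templates <- function(config) {
  tmpl <- synthetic_templates()
  for (task in names(tmpl)) {
    k <- config$n_classes[[task]]
    if (task == "subsite") {
      # keep the two subsites of each retained site, in pool order
      keep <- seq_len(2L * config$n_classes[["site"]])
      tmpl[[task]]$classes <- tmpl[[task]]$classes[keep]
    } else {
      tmpl[[task]]$classes <- tmpl[[task]]$classes[seq_len(k)]
    }
  }
  tmpl
}

#' Label schema of the synthetic generator
#'
#' @param config A `fastmpn_generator_config`.
#' @return A `fastmpn_schema` whose tasks and class registries match what
#'   [generate_corpus()] emits.
#' @export
synthetic_schema <- function(config = generator_config()) {
  tmpl <- active_templates(config)
  do.call(label_schema, lapply(tmpl, function(t) names(t$classes)))
}

power_law_prior <- function(k, gamma) {
  p <- seq_len(k)^(-gamma)
  p / sum(p)
}

#' Generate a synthetic pathology-report-like corpus
#'
#' Seeded-deterministic. Each document renders one phrase per non-omitted
#' task, drawn from that class's template family with the configured variation
#' operators applied independently, interleaved with filler sentences and
#' (optionally) noise tokens. Class priors follow the configured power law;
#' the subsite label is always consistent with the site label (subsites are
#' nested two-per-site). The latent template choices that produced each
#' document are kept in a `latent` list-column for debugging.
#'
#' @param config A `fastmpn_generator_config`.
#' @return A corpus tibble (`doc_id`, `text`, one label column per task, plus
#'   `latent`) ready for [write_corpus()] / [fastmpn_fit()].
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "fastmpn_generator_config"))
  tmpl <- active_templates(config)
  fillers <- synthetic_fillers()
  tasks <- names(tmpl)

  withr::with_seed(config$seed, {
    n <- config$n_docs
    site_k <- config$n_classes[["site"]]
    site_prior <- power_law_prior(site_k, config$imbalance)
    within_prior <- power_law_prior(2L, config$imbalance)
    priors <- lapply(tasks, function(task) {
      power_law_prior(length(tmpl[[task]]$classes), config$imbalance)
    })
    names(priors) <- tasks

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      labels <- list()
      site_idx <- sample.int(site_k, 1L, prob = site_prior)
      labels$site <- site_idx
      labels$subsite <- 2L * (site_idx - 1L) + sample.int(2L, 1L, prob = within_prior)
      for (task in setdiff(tasks, c("site", "subsite"))) {
        labels[[task]] <- sample.int(length(tmpl[[task]]$classes), 1L,
                                     prob = priors[[task]])
      }

      phrases <- character(0)
      latent <- list()
      out_labels <- stats::setNames(rep(NA_character_, length(tasks)), tasks)
      for (task in tasks) {
        omitted <- stats::runif(1) < config$p_omit
        cls_idx <- labels[[task]]
        cls_name <- names(tmpl[[task]]$classes)[cls_idx]
        if (omitted) {
          latent[[task]] <- list(class = cls_name, omitted = TRUE)
          next
        }
        forms <- tmpl[[task]]$classes[[cls_idx]]
        form_idx <- 1L
        if (length(forms) > 1L && stats::runif(1) < config$p_synonym) {
          form_idx <- sample.int(length(forms) - 1L, 1L) + 1L
        }
        value <- forms[[form_idx]]
        field <- tmpl[[task]]$field
        hint <- NULL
        if (stats::runif(1) < config$p_parenthetical) {
          hint <- tmpl[[task]]$hints[[sample.int(length(tmpl[[task]]$hints), 1L)]]
        }
        inverted <- stats::runif(1) < config$p_invert
        phrase <- if (is.null(hint)) {
          paste0(paste(field, collapse = " "), ": ", paste(value, collapse = " "))
        } else {
          paste0(paste(field, collapse = " "), " (", paste(hint, collapse = " "),
                 "): ", paste(value, collapse = " "))
        }
        if (inverted) {
          toks <- tokenize(phrase)
          phrase <- paste(rev(toks), collapse = " ")
        }
        phrases <- c(phrases, phrase)
        out_labels[[task]] <- cls_name
        latent[[task]] <- list(class = cls_name, form = form_idx,
                               hint = !is.null(hint), inverted = inverted,
                               omitted = FALSE)
      }
      n_fill <- sample.int(config$filler_range[2] - config$filler_range[1] + 1L, 1L) +
        config$filler_range[1] - 1L
      fill <- if (n_fill > 0L) fillers[sample.int(length(fillers), n_fill, replace = TRUE)] else character(0)
      parts <- c(phrases, fill)
      parts <- parts[sample.int(length(parts))]
      text <- paste(parts, collapse = ". ")
      if (nchar(text) == 0L) text <- fillers[1]
      if (config$noise_rate > 0) {
        toks <- tokenize(text)
        keep <- character(0)
        for (tk in toks) {
          keep <- c(keep, tk)
          if (stats::runif(1) < config$noise_rate) {
            keep <- c(keep, paste0("xq", sample.int(50L, 1L)))
          }
        }
        text <- paste(keep, collapse = " ")
      }
      row <- tibble::tibble(doc_id = sprintf("doc%06d", i), text = text)
      for (task in tasks) row[[task]] <- out_labels[[task]]
      row$latent <- list(latent)
      rows[[i]] <- row
    }
    dplyr::bind_rows(rows)
  })
}

#' Recover labels from synthetic text by rule matching
#'
#' For each task, a document matches a class when the token multiset of one of
#' that class's template forms is contained in the document's tokens. With the
#' generator's variation operators on but noise off, exactly one class matches
#' per rendered field, so the matcher recovers every generated label — the
#' guarantee that the synthetic classification task is solvable.
#'
#' @param corpus A corpus tibble with `text`.
#' @param config The `fastmpn_generator_config` the corpus was generated with.
#' @return A tibble `doc_id` plus one recovered-label column per task (`NA`
#'   when no class form matches, e.g. for omitted fields).
#' @export
recover_labels <- function(corpus, config = generator_config()) {
  tmpl <- active_templates(config)
  out <- tibble::tibble(doc_id = corpus$doc_id)
  toks_all <- tokenize(corpus$text, simplify = FALSE)
  for (task in names(tmpl)) {
    classes <- tmpl[[task]]$classes
    rec <- vapply(toks_all, function(toks) {
      tab <- table(toks)
      hits <- names(classes)[vapply(classes, function(forms) {
        any(vapply(forms, function(form) {
          need <- table(form)
          all(names(need) %in% names(tab)) && all(tab[names(need)] >= need)
        }, logical(1)))
      }, logical(1))]
      if (length(hits) == 1L) hits else NA_character_
    }, character(1))
    out[[task]] <- rec
  }
  out
}

#' Summarize a corpus
#'
#' @param corpus A corpus tibble.
#' @param schema A `fastmpn_schema` naming the label columns to histogram.
#' @return A list: `class_counts` (tibble `task`, `class`, `n`), `vocab_size`
#'   (distinct token count), `mean_length` (mean tokens per document),
#'   `n_documents`.
#' @export
corpus_summary <- function(corpus, schema) {
  stopifnot(is.data.frame(corpus), inherits(schema, "fastmpn_schema"))
  if (nrow(corpus) == 0L) {
    return(list(class_counts = tibble::tibble(task = character(), class = character(),
                                              n = integer()),
                vocab_size = 0L, mean_length = NaN, n_documents = 0L))
  }
  counts <- list()
  for (task in schema_tasks(schema)) {
    if (!task %in% names(corpus)) next
    lab <- corpus[[task]][!is.na(corpus[[task]])]
    if (length(lab) == 0L) next
    tab <- table(lab)
    counts[[task]] <- tibble::tibble(task = task, class = names(tab),
                                     n = as.integer(tab))
  }
  toks <- tokenize(corpus$text, simplify = FALSE)
  list(
    class_counts = dplyr::bind_rows(counts),
    vocab_size = length(unique(unlist(toks, use.names = FALSE))),
    mean_length = mean(lengths(toks)),
    n_documents = nrow(corpus)
  )
}
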