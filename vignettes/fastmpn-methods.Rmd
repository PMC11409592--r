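---
title: "Message passing over graphs of words: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Message passing over graphs of words: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastmpn)
```

## The model

A document is represented as a graph of words: one node per *token position*,
with directed edges both ways between every pair of positions at distance
1..`d`, plus a self edge on every node. Embeddings are shared by word type —
two occurrences of "grade" read the same embedding row — but each occurrence
is its own node, so repeated words contribute multiply to the sum readout.
This reconciles the two views of a GOW (nodes as unique words vs. messages
over the nearest `p` words *in the text*); the positional reading is the one
that makes mini-batched computation regular.

Three aggregation modes are implemented over this graph:

* **max** (`message_max()`): the reference architecture. Each node receives
  the dimension-wise maximum of `e_an * r_a` over its incoming edges. The
  maximum makes gather-style vectorization awkward and is retained for
  comparison, not speed.
* **dense sum** (`message_dense()`): `M_n = Σ_i e_in r_i` realized as a full
  sparse-adjacency matrix product. Conceptually the sum runs over every node
  with zero weight on non-adjacent pairs; it exists as the independent oracle
  for the fast path.
* **sparse sum** (`message_sparse()`, the default): the identical sum
  computed by gathering edge-indexed embedding rows and edge weights into
  flat arrays and scatter-summing by target node (`rowsum()` is the scatter
  primitive). The two sum modes agree up to summation-order rounding; the
  test suite requires max elementwise deviation below 1e-5 over random
  graphs and in practice sees ~1e-15.

Edge weights are scalars shared *globally* by ordered word pair, via a
corpus-level registry built from the training split only. Pairs never seen
in training share one trainable *public* fallback weight, and unknown words
map to an unknown-word sentinel embedding; together these make the model
deployable to documents (and registries) never seen during training, which
is the deciding advantage over corpus-graph formulations that put documents
in the graph.

The readout sums the final node states over the document (permutation
invariant by construction) and applies one linear head plus softmax per
task: multi-task learning with a shared trunk. Single-task mode trains the
same architecture on one head.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 2 | co-occurrence window (tokens); also the message neighborhood |
| `w` | 300 | embedding length; 16–64 suffices at synthetic scale |
| `edge_min_count` | 1 | corpus count below which a pair gets no private weight |
| `self_loops` | TRUE | self pair `(w, w)` registered per word; carries retained state |
| `use_eta` | FALSE | per-word retention coefficient squashed into (0, 1) |
| `activation` | identity | head nonlinearity inside the softmax |
| `dropout` | 0 | dropout on the pooled document vector (training only) |
| `learning_rate` | 1e-3 | adaptive moment estimation step size |
| `batch_size` | 256 | documents per gradient step |

Notes on the open choices these defaults settle:

* **Self loops vs. retention.** The reference update interpolates
  `r_new = (1 − η) M + η r_old` with trainable η. The weighted-sum
  formulation already includes the node itself in its neighborhood sum, so
  the self edge's weight plays η's role; η is therefore off by default and
  available (`use_eta = TRUE`) for reference-mode fidelity. Both paths are
  covered by the finite-difference gradient checks.
* **Head activation.** With a rectifier inside `softmax(σ(Vx + b))`, every
  head coordinate with a non-positive pre-activation has exactly zero
  gradient; if all coordinates of a head go non-positive simultaneously the
  head is stuck at the uniform distribution forever. The linear form avoids
  this failure mode entirely and is the default; `activation = "relu"`
  reproduces the literal reference readout.
* **Tokenization.** Lowercased maximal alphanumeric runs; punctuation and
  hyphens separate ("g1-3" → "g1", "3"). Digits are kept because grade
  labels are numeric. No stemming, stop-words or subwords. Truncation
  defaults to the first 1500 tokens (diagnosis fields lead these reports);
  tail truncation is available.
* **Initialization.** Embeddings zero-mean with scale `1/sqrt(w)`; edge
  weights `1 + N(0, 0.01)` so the initial pass is close to an unweighted
  window sum; heads small-random with zero bias; the padding row is frozen
  at zero and excluded from pooling.
* **Optimizer.** Adaptive moment estimation (β₁ = 0.9, β₂ = 0.999), summed
  cross-entropy over tasks with equal weights, missing labels masked to
  exactly zero. The 1e-3 default step is conservative; the synthetic-scale
  runs in the tests and the acceptance script use 0.01, which converges in
  ~10 epochs at `w = 32`. Early stopping watches the validation aggregate
  (mean of all per-task micro/macro F1) with patience 5 and returns the
  best-validation parameters.

Gradients for all parameter blocks — embedding rows, shared edge weights,
retention, heads — are derived and implemented by hand (the scatter-sum's
adjoint is a gather, and vice versa), and verified against central finite
differences at relative error below 1e-4 in every mode.

## Evaluation conventions

Micro-F1 pools TP/FP/FN counts over classes; for single-label multiclass
prediction it equals accuracy, and the tests assert that identity on random
instances. Macro-F1 averages per-class F1 unweighted over the classes
present in truth or predictions; a 324- or 572-class registry can never be
fully represented in a finite test set, so full-registry averaging (which
only adds zeros) is available via the `classes` argument rather than being
the default. Per-class F1 with a zero denominator is defined as 0. The
12-score aggregate is a plain mean with no clinical meaning; it exists to
compare models with one number, and `aggregate_scores()` reproduces the
published benchmark averages (0.7014 multi-task vs. 0.6935 convolutional
baseline) from the shipped per-task score table.

## What the synthetic generator emulates — and what it does not

Real registry text cannot be shared, so the generator emulates its
*structure*: one semi-structured phrase per task drawn from a class-specific
template family; variation operators applied independently (word inversion,
parenthetical insertion such as "histologic grade (mbr): 3", synonym
substitution such as "3" / "g3" / "iii" / "poorly differentiated"); filler
sentences; a power-law class prior (exponent 1.5) giving severe imbalance;
subsite labels nested two-per-site so two tasks are strongly correlated; and
field omission (5% default) producing missing labels that exercise the loss
mask. Class counts (6/12/4/10/3/5) keep desk-scale runtime while preserving
the few-class vs. many-class contrast of the real tasks.

Two properties make the generated benchmark meaningful. First, with noise
off, labels are a deterministic function of the text: a rule-based matcher
over the template families (`recover_labels()`) recovers every label, so
near-perfect model F1 is achievable and the training target is honest.
Second, inverted renderings preserve the document's unordered word-pair
multiset at `d = 1`, which is exactly the robustness the GOW representation
claims.

What passing on this corpus does **not** show: real reports have much larger
vocabularies (hundreds of thousands of word types), hundreds of classes per
task with genuinely ambiguous boundary cases, label noise from human
annotation, and correlations between all six fields — none of which the
generator reproduces. Synthetic scores near 1.0 validate the machinery, not
clinical performance; the published benchmark scores sit near 0.70 for good
reason.

## Numerical choices and degenerate inputs

* Sparse and dense sums differ only by floating-point summation order; the
  equivalence tests use a 1e-5 elementwise band.
* Softmax subtracts the row maximum before exponentiation; cross-entropy
  clamps probabilities at the smallest positive double before `log`.
* Empty documents (zero tokens after tokenization) are rejected at encoding
  with the offending `doc_id`; a node with no incoming edges is a structural
  error in max mode (impossible with self loops on).
* Ties in argmax prediction resolve to the first (lowest-index) class.
* Registry identifiers are assigned in sorted pair order and the vocabulary
  breaks frequency ties lexicographically, so both are deterministic for a
  given corpus; training is bit-reproducible from its seed on one worker.
* Checkpoints embed a format version and refuse to load any other version
  or a damaged file.

## Problem sizes used in the shipped runs

The test suite and the acceptance script run entirely on synthetic data:
the learning-behavior run uses 5,000 documents (4,000 train / 1,000
validation), `d = 2`, `w = 32`, batch 256, step 0.01, at most 20 epochs with
patience 5 — about half a minute on one CPU — and requires every task's
validation micro-F1 to reach 0.95 (observed ≈ 0.997). Equivalence and
oracle checks use 100 random graphs of up to 50 nodes and `w ≤ 16`. These
sizes are the package's chosen desk-scale study conditions; the architecture
itself has no dependence on them.

## Known limitations

Single-worker CPU training only — no data parallelism, no GPU. One message
passing layer is the default and the only depth exercised by the shipped
runs (deeper stacks are implemented and gradient-checked but not studied).
The max-mode reference is trainable but quadratic-ish in bookkeeping and
meant for small comparisons. No attempt is made to mimic real coding
systems (ICD-O-3) or real site/histology vocabularies.
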