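---
title: "Risk-factor extraction and CVD prediction: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-factor extraction and CVD prediction: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrisk)
```

## The problem

Electronic medical records (EMRs) are free text. Most of a record is
irrelevant to cardiovascular risk; the clinically loaded content is a small
set of risk-factor statements — hypertension, diabetes, smoking, and so on —
each of which holds at some time relative to the record (an attribute we
call *temporal*: Continue, During, After, Before; Age and Gender carry the
placeholder None). `emrisk` implements a two-stage pipeline:

1. a **character-level BiLSTM-CRF sequence labeler** extracts risk-factor
   mentions and their temporal attributes under a BIO tagging scheme, and
2. a **deep pyramid character-level CNN** reads the extracted
   (mention, label) units and predicts a binary CVD label.

The division of labor matters: stage one discards the irrelevant bulk of
the record, so stage two trains on short, dense inputs.

## Stage one: BiLSTM-CRF

Each character is embedded (`embed_sequence()`), encoded by a forward and a
backward LSTM with separate parameters (`bilstm_encode()`), and projected
through a `tanh` layer to per-tag emission scores
$P_{t,j} = \tanh(W_e h_t)_j$ (`emission_scores()`). The emission matrix is
bounded in $(-1, 1)$
by construction; discrimination between tag paths therefore leans on the
learned transition matrix $T$, which carries a distinguished start row.
A tag path $y$ scores

$$s(X, y) = \sum_{i=1}^{n} \left( T_{y_{i-1}, y_i} + P_{i, y_i} \right),$$

and the model is a linear-chain CRF: path probabilities are
$e^{s(X,y)} / \sum_{\tilde y} e^{s(X,\tilde y)}$, the log-normalizer is
computed exactly by the forward recursion in log space
(`crf_log_partition()`), and decoding is exact Viterbi (`crf_viterbi()`),
with ties broken toward the lowest tag index so decoding is deterministic.
Training maximizes the log-likelihood of gold paths; the gradients are the
classical forward–backward marginals. The training path computes them with
the scaled (per-step renormalized) forward–backward recursion — one
matrix–vector product per position instead of a log-sum-exp over the full
transition matrix — which is numerically safe because emissions are
tanh-bounded and transitions stay moderate under gradient clipping; the
summed pairwise marginals for the transition gradient factorize into a
single cross-product per sentence. The exported `crf_log_partition()`
keeps the fully general log-space recursion (stable for scores up to
$\pm 10^3$).

The tag inventory is 12 risk factors crossed with the temporal codes —
10 types × {C, D, A, B} plus Age/Gender × {N} — giving 42 entity codes and
85 BIO tags. At decoding time an `I-x` whose predecessor carries a
different code is repaired to `B-x`; repairing (rather than dropping)
preserves recall, and the rule is exercised directly by the tests.

Design choices that the architecture left open:

* **Hidden size** is not dictated by the shared hyper-parameter table; we
  default to $H = 100$, matching the embedding dimension $d_w = 100$.
* **Optimizer.** Training uses Adam with one sentence per step, global
  gradient-norm clipping at 5, and the exponential schedule
  $lr \cdot 0.99^{g/500}$. The classifier's table value $lr = 0.001$
  proved a poor default for the labeler: with bounded emissions the CRF
  needs thousands of steps before the transition structure emerges, and at
  $lr = 0.001$ the model is still near-uniform after several epochs on a
  500-sentence corpus. The labeler therefore defaults to $lr = 0.005$,
  which reaches the same optimum several times sooner; the value is
  configurable and the schedule shape is unchanged.
* **No hard BIO constraints** are imposed on $T$: the transition matrix
  must learn to avoid invalid transitions, matching the plain CRF
  formulation.
* Character embeddings are fine-tuned during NER training by default; the
  `<PAD>` row stays frozen at zero.

## Character embeddings

`train_char_embeddings()` is a single-threaded skip-gram with negative
sampling (window 5, 5 noise draws from the unigram distribution raised to
3/4, 5 epochs by default — conventional values; none are dictated by the
architecture). A dictionary of risk-factor surface strings can be injected:
each entry is appended to the training stream 10× as its own sentence, so
the characters of one risk factor co-occur tightly. The returned matrix is
the **sum of the input and output matrices**. This choice is deliberate:
the dictionary-injection effect is a first-order (co-occurrence)
association, which lives in the input–output alignment, not in the
input–input geometry; summing the two matrices (as GloVe does, and as
word2vec offers as an option) makes that structure visible to cosine
similarity. On small corpora all trained vectors also share a common drift
direction, so `embedding_cosine(..., center = TRUE)` removes column means
before comparing; the package's co-occurrence tests use the centered form.

## Stage two: the pyramid CNN

The classifier input is a `UnitSequence`: one fixed-width 7-cell unit per
extracted mention — up to 6 surface characters (padded) plus one label
token `B-<code>` carrying the type and temporal attribute. A region size of
$k = 7$ therefore covers exactly one unit, $k = 14$ two units.

The network is:

* **Region embedding** (`region_embed()`): $Wx + b$ at every position,
  where $x$ is the $kv$-dimensional concatenation of $k$ one-hot vectors
  (edges padded with `<PAD>`). No nonlinearity — activation is delayed to
  the next layer's pre-activation. For even $k$ the window splits
  floor/ceil left/right.
* **Convolution blocks** (`conv_block()`): two pre-activation convolution
  layers $W\sigma(x) + b$ with $\sigma(x) = \max(x, 0)$, kernel 3,
  same-length zero padding, wrapped in an identity shortcut $z + f(z)$.
  Because every layer preserves both the feature-map count ($m = 250$ by
  default) and the length, the shortcut needs no projection — the two
  operands of every addition are shape-equal by construction, which the
  tests assert structurally.
* **Downsampling** (`downsample()`): max-pooling of size 3, stride 2,
  between blocks. Windows are centered at every other position with
  $-\infty$ padding at both ends, so the output length is exactly
  $\lceil n/2 \rceil$ — each pooling halves the representation. Pooling
  layers stop being inserted once the length would drop below 2; remaining
  blocks run at the floor length.
* **Head**: global max-pool to one $m$-vector, dropout, a linear map to two
  scores, and a normalized exponential. With all weights zero the head
  yields (0.5, 0.5).

Depth accounting reads $d_p = 15$ as weight layers: one region-embedding
layer plus 7 blocks × 2 convolution layers. With the feature-map count
fixed, the block at level $\ell$ processes $\lceil n / 2^\ell \rceil$
positions at $2 \cdot ks \cdot m^2$ multiply–accumulates per position
(`count_macs()`), so consecutive blocks cost exactly half as much at
power-of-two lengths and the total is bounded by about twice the first
block. The ceiling adds at most one position per block, so for arbitrary
lengths the exact bound is
$\sum_b \mathrm{MACs}_b \le 2\,\mathrm{MACs}_1 + (B - 1) \cdot 2\,ks\,m^2$;
for lengths $\ge 384$ with 7 blocks the plain $2\times$ bound holds as
stated. `receptive_field()` tracks the covered span and the cumulative
stride: after $L$ poolings the stride is $2^L$ and the receptive field
grows in the order of $2^L$ — the mechanism by which a downsampled CNN
represents long-range associations cheaply.

**Dropout placement** is not dictated by the hyper-parameter table (which
gives only the keep rate 0.5). We experimented with dropout after the
region embedding, on the final pooled vector, and at both sites, on a
held-out tuning corpus of the synthetic planted-rule task; placement on
the final vector only gave the best held-out accuracy, and
region-embedding dropout (which deletes half of the one-hot evidence per
window) was clearly harmful at small $m$. The implementation applies
dropout to the final vector only.

**Regularization for small corpora.** At a few hundred training
documents the network happily memorizes surface combinations instead of
learning the document-level rule, so three further devices are built in
(all tuned on a generator corpus with a different seed than the
recovery experiments, then frozen):

* *Unit permutation* (`permute_units`, default on): each document's
  7-cell units are re-ordered at every training presentation. The unit
  sequence encodes an unordered set of extracted risk factors, so the
  label is permutation-invariant and the augmentation is exact.
* *Word dropout* (`word_dropout`, default 0.5): input tokens are
  replaced by `<UNK>` at random during training, making memorized token
  combinations unreliable.
* *Embedding-based initialization*: when pre-trained character
  embeddings are passed to `train_classifier()`, the region-embedding
  columns of known tokens start as a seeded random projection of their
  embedding vectors (one projection per window offset). Surface variants
  of the same risk factor — drawn together by dictionary-injected
  skip-gram training — then produce similar region activations from the
  first step, which measurably improves sample efficiency. The one-hot
  input contract is unchanged.

A `class_weights = "balanced"` option reweights the loss by inverse
class frequency; the default is unweighted, which matches the fixed 0.5
decision threshold under skewed prevalence.

**Training** is minibatch Adam (batch 64), cross-entropy loss, the same
exponential learning-rate schedule, global-norm clipping at 5, and
seed-deterministic shuffling. A single-class dataset trains with a warning.

## The synthetic-EMR generator

The real corpora behind this architecture are private clinical text, so
the package ships a generator (`generate_corpus()`) that reproduces the
statistical structure both models assume, with an abstract alphabet —
lowercase filler characters (geometric run lengths), fixed uppercase
lexicon surfaces per risk factor (2–4 strings of 2–4 characters each), and
BIO tags that exactly cover the planted spans. Two generator choices
deserve explanation:

* **Temporal markers.** Each mention surface ends in one marker character
  per temporal code (`+ * > < #` for C, D, A, B, N), inside the tagged
  span. Without it the same surface string would appear under different
  temporal tags and no character-level model could recover the attribute —
  the extraction task would be information-theoretically capped well below
  the recovery targets. Real clinical text signals temporality with
  context words; a single in-span marker is the minimal analogue.
* **The planted rule.** A document is positive iff at least $\theta = 3$
  **distinct** risk-factor types occur with an active temporal attribute
  ({Continue, During}). Distinctness (not mention count) is what the
  classifier must learn; the rule is deterministic, so every generated
  label is consistent by construction and the test suite asserts it
  exhaustively.

Defaults: 659 documents split 461/66/132 (train/dev/test, the reference
corpus proportions), target CVD prevalence 0.8 (527 of 659 records in the
reference corpus are positive), Poisson(5) mentions per document,
geometric filler runs with $p = 0.3$ over a 20-character alphabet.
Prevalence is steered by per-document rejection sampling (cap 10 000
tries) against Bernoulli targets, so the realized prevalence concentrates
within a few points of the target; an infeasible prevalence/θ combination
errors instead of silently biasing.

What the generator does *not* emulate: real Chinese medical phraseology,
negation, section structure, misspellings, or annotation noise. Passing
the recovery tests shows the models and training loop are correct and
that the architecture can extract and aggregate planted structure; it
says nothing about clinical-grade accuracy on real EMRs.

## Problem sizes and budgets

The recovery experiments train on 500 synthetic sentences/documents and
evaluate on 200 held-out ones, with the whole suite sized for a single
CPU. The embedding stage runs skip-gram over the training sentences plus
the risk-factor dictionary; the labeler trains 16 epochs of per-sentence
Adam steps on those embeddings (fine-tuned); the reduced classifier
(m = 32, 3 blocks) trains 120 epochs of batch-64 Adam. The full-size
model (m = 250, 7 blocks) is exercised for forward passes, cost
accounting and identity properties, not trained in the tests.

Pre-trained embeddings matter for both stages. For the labeler they are
the difference between slow, incomplete convergence and near-perfect
held-out extraction at the same step budget — consistent with the
design's emphasis on domain-trained character vectors. For the reduced
classifier they lift held-out accuracy substantially, but its
planted-rule task — counting *distinct* active risk-factor types against
a threshold — remains the sample-hungry part of the suite: the same
model trained on six times the documents closes most of the remaining
gap, and a logistic model given oracle presence features solves the task
almost perfectly, so the residual errors at 500 documents reflect the
sample efficiency of learning presence-and-count features end to end,
not a ceiling of the data or the architecture.

## Numerical choices

* Log-sum-exp everywhere in the CRF; scores up to $\pm 10^3$ are safe.
* Viterbi and pooling argmax ties break toward the lowest index — decoding
  and gradient routing are deterministic.
* Forget-gate biases initialize to 1; other weights uniform in
  $\pm$ `init_scale`.
* `<PAD>` embedding rows are zeroed after every update.
* Gradients are clipped by global norm (5.0) before every Adam step.
* Degenerate inputs: empty sentences decode to no mentions; documents with
  zero extracted mentions are classified 0 with a `no_evidence` flag
  (a documented convention — the classifier never sees an empty input).

## Known limitations

* The labeler's emission scores are tanh-bounded; with 85 tags this makes
  early training slow (the CRF must first learn transitions), which is why
  the labeler's learning rate default differs from the classifier's.
* Pure-R training is practical at the package's problem sizes but not at
  clinical-corpus scale; the implementation is written for exactness and
  reproducibility, not throughput.
* Exact-match entity scoring (span + type + temporal) is the strictest
  reading; partial-overlap credit is not implemented.
* The end-to-end probability is not calibrated; 0.5 is the only decision
  threshold offered.
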