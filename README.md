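# emrisk

Two-stage prediction of cardiovascular disease (CVD) from free-text
electronic medical records (EMRs), implemented as a tested, reusable R
package:

1. **Risk-factor extraction** — a character-level BiLSTM-CRF sequence
   labeler tags each character with a BIO label encoding one of twelve CVD
   risk factors (Hypertension, Diabetes, Smoking, …) together with a
   temporal attribute (Continue, During, After, Before; None for
   Age/Gender). Inference is exact: the linear-chain CRF scores a tag path
   as

   s(X, y) = Σᵢ ( T[yᵢ₋₁, yᵢ] + P[i, yᵢ] ),

   with emissions P = tanh(Wₑ hₜ) from the BiLSTM states, the
   log-normalizer from the forward recursion, and decoding by Viterbi.

2. **CVD classification** — extracted (mention, label) pairs are packed
   into fixed-width 7-cell units (6 surface characters + 1 label token) and
   read by a deep pyramid character-level CNN: a text region embedding
   (Wx + b over the kv-dimensional concatenation of k one-hot vectors),
   stacked two-layer pre-activation convolution blocks (W·σ(x) + b,
   σ = max(x, 0)) with identity shortcuts z + f(z), and size-3 stride-2
   max-pool downsampling with the feature-map count fixed (250 by
   default), ending in a global max-pool and a two-way softmax head.
   Because the feature-map count never changes, each downsampling halves
   the per-block computation, the total stays bounded by about twice the
   first block, and the receptive field grows like 2^L after L poolings —
   the package ships analytic accounting for both claims (`count_macs()`,
   `receptive_field()`).

The clinical corpora this architecture was designed for are private, so
the package includes a seeded synthetic-EMR generator
(`generate_corpus()`) that reproduces the statistical structure both
models assume — filler text with planted, BIO-tagged risk-factor mentions
and a document label produced by a known planted rule — making every stage
trainable and testable offline. Supporting modules cover skip-gram
character-embedding training with risk-factor dictionary injection,
CoNLL-style corpus IO, word2vec-format embedding IO, JSON-lines document
IO, and entity/classification metrics.

Everything is implemented in plain R (BLAS-backed matrix operations),
including full backpropagation for both networks and the CRF
forward–backward gradients — no deep-learning framework required.

## Worked example

```r
library(emrisk)

# a synthetic corpus: 120 documents, default prevalence 0.8, seed 13
corp <- generate_corpus(synth_config(n_docs = 120, seed = 13))
corp
#> <synth_corpus> train/dev/test = 84/12/24  prevalence = 0.817

# skip-gram character embeddings over the training text, with every
# risk-factor surface injected as a dictionary entry
emb <- train_char_embeddings(lapply(corp$train$sentences, `[[`, "chars"),
                             dictionary = risk_factor_dictionary(),
                             dim = 100, seed = 13)

# train the extractor on the annotated sentences
lab <- train_labeler(corp$train$sentences, embeddings = emb, seed = 13)
lab
#> <emrisk_labeler> vocab 51 chars, 85 tags, H = 100
#>   final mean -loglik: 4.8898

# extract mentions from a held-out document
doc <- corp$test$documents[[1]]
mentions <- extract_mentions(lab, doc$text)
mentions[[1]]
#> <mention> Sm/C [16,19) "OP+"

# train the classifier on gold (mention, label) units
uv <- build_unit_vocab(vapply(corp$train$documents, `[[`, character(1), "text"))
ds <- lapply(seq_along(corp$train$documents), function(i) {
  list(units = mentions_to_units(corp$train$mentions[[i]], uv),
       label = corp$train$documents[[i]]$label)
})
ds  <- ds[vapply(ds, function(d) length(d$units) > 0, logical(1))]
clf <- train_classifier(ds, uv, endcnn_config(m = 32, depth = 7, epochs = 120),
                        seed = 13, embeddings = emb)

# end-to-end prediction
predict_cvd(doc$text, lab, clf)$label
#> [1] 1
```

The first mention above reads: a Smoking mention with temporal attribute
Continue at characters 16–19, whose surface `"OP+"` is a lexicon string
plus the Continue marker. The labeler's per-epoch mean negative
log-likelihood (printed with `verbose = TRUE`) must decrease across
epochs; `predict_cvd()` returns the label, the probability pair (always
summing to 1), the extracted mentions, and a `no_evidence` flag for
documents from which nothing was extracted (classified 0 by convention).

A thin command-line surface over the same functions is installed at
`inst/cli/emrisk.R` with subcommands `synth`, `train-embeddings`,
`train-ner`, `extract`, `train-clf`, `predict`, `evaluate`; shared flags
`--config <yaml>`, `--seed <int>`, `--out <dir>`.

## Scope

The package implements and tests the architecture; it does not attempt to
reproduce scores reported on private clinical corpora, ship comparison
baselines (SVM, plain LSTM, CRF-only), or provide clinically validated
text imputation (only a minimal documented normalizer). See
`vignettes/methods.Rmd` for the models, the generator's assumptions, and
the design decisions taken where the architecture left choices open.
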