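#' Risk-factor mention
#'
#' One extracted (or gold) risk-factor occurrence: its type, temporal
#' attribute, character span and surface string. Spans are 0-based,
#' half-open \code{[start, end)}, in characters of the (normalized) text.
#'
#' @param type risk-factor code (e.g. \code{"Hy"})
#' @param temporal one-letter temporal code (C, D, A, B or N)
#' @param start,end 0-based half-open span, \code{0 <= start < end}
#' @param surface the mention's surface string
#' @return object of class \code{risk_factor_mention}
#' @export
risk_factor_mention <- function(type, temporal, start, end, surface = "") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (!(start >= 0L && start < end)) {
    stop("invalid span [", start, ", ", end, ")")
  }
  structure(list(type = type, temporal = temporal,
                 start = start, end = end, surface = surface),
            class = "risk_factor_mention")
}

#' @export
print.risk_factor_mention <- function(x, ...) {
  cat(sprintf("<mention> %s/%s [%d,%d) \"%s\"\n",
              x$type, x$temporal, x$start, x$end, x$surface))
  invisible(x)
}

#' Configuration of the BiLSTM-CRF labeler
#'
#' Embedding dimension \code{d_w} 100 and the decay schedule (rate 0.99
#' per 500 steps) follow the shared hyper-parameter table. The hidden size
#' is a free choice; it defaults to 100, matching \code{d_w}. Optimization
#' is Adam with one sentence per step and global gradient-norm clipping at
#' 5; the base learning rate defaults to 0.005 — with tanh-bounded
#' emissions the CRF learns its transition structure several times faster
#' there than at the classifier's table value 0.001, with no loss in final
#' fit (see the methods vignette).
#'
#' @param d_w character embedding dimension
#' @param hidden LSTM hidden size per direction
#' @param lr base learning rate
#' @param decay_rate,decay_steps exponential learning-rate schedule
#' @param clip global gradient-norm ceiling
#' @param epochs training epochs
#' @param init_scale uniform init half-width for network weights
#' @param fine_tune_embeddings update embedding rows during training
#' @return list of class \code{labeler_config}
#' @export
labeler_config <- function(d_w = 100L, hidden = 100L, lr = 0.005,
                           decay_rate = 0.99, decay_steps = 500L,
                           clip = 5.0, epochs = 16L, init_scale = 0.08,
                           fine_tune_embeddings = TRUE) {
  structure(list(d_w = as.integer(d_w), hidden = as.integer(hidden),
                 lr = lr, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps), clip = clip,
                 epochs = as.integer(epochs), init_scale = init_scale,
                 fine_tune_embeddings = isTRUE(fine_tune_embeddings)),
            class = "labeler_config")
}

#' Emission scores from BiLSTM states
#'
#' The tanh layer on top of the BiLSTM: \eqn{e_t = \tanh(W_e h_t)} for
#' every position, giving per-tag confidence scores strictly inside
#' (-1, 1). Rows of the result index positions, columns tags.
#'
#' @param h n x 2H matrix of BiLSTM hidden states
#' @param w_e (number of tags) x 2H emission weight matrix
#' @return n x (number of tags) emission score matrix
#' @export
emission_scores <- function(h, w_e) {
  if (ncol(h) != ncol(w_e)) {
    stop("hidden states are ", ncol(h), "-dimensional but the emission ",
         "matrix expects ", ncol(w_e))
  }
  tanh(h %*% t(w_e))
}

#' Train the BiLSTM-CRF risk-factor extractor
#'
#' Maximizes the log-probability of the gold tag paths: each sentence is
#' embedded, encoded by the BiLSTM, mapped to emission scores by the tanh
#' layer, and scored by the CRF; gradients flow through all layers
#' (including the embedding rows when \code{fine_tune_embeddings}).
#' Training is seed-deterministic on a single thread.
#'
#' @param corpus list of [annotated_sentence()]
#' @param vocab optional \code{char_vocab}; built from the corpus if NULL
#' @param embeddings optional pre-trained embeddings, either the list
#'   returned by [train_char_embeddings()] or a v x d_w matrix aligned with
#'   \code{vocab}; random initialization if NULL
#' @param config a [labeler_config()]
#' @param scheme a [tag_scheme()]
#' @param seed RNG seed
#' @param verbose print per-epoch mean loss
#' @return object of class \code{emrisk_labeler} with the trained
#'   parameters and a per-epoch \code{loss_history} (mean negative
#'   log-likelihood)
#' @export
train_labeler <- function(corpus, vocab = NULL, embeddings = NULL,
                          config = labeler_config(), scheme = tag_scheme(),
                          seed = 1L, verbose = FALSE) {
  if (length(corpus) == 0L) stop("empty training corpus")
  for (s in corpus) validate_tags(s$tags, scheme)

  if (!is.null(embeddings) && is.list(embeddings) &&
      !is.null(embeddings$vocab)) {
    vocab <- embeddings$vocab
    emb <- embeddings$matrix
  } else if (is.null(vocab)) {
    vocab <- build_vocab(lapply(corpus, `[[`, "chars"))
    emb <- NULL
  } else {
    emb <- embeddings
  }

  set.seed(as.integer(seed))
  v <- length(vocab$tokens)
  d <- config$d_w
  h <- config$hidden
  m <- length(scheme$tags)
  if (is.null(emb)) {
    emb <- matrix(stats::runif(v * d, -config$init_scale,
                               config$init_scale), v, d)
    emb[1L, ] <- 0
  } else {
    if (nrow(emb) != v) stop("embedding matrix does not match vocabulary")
    d <- ncol(emb)
    config$d_w <- d
  }
  params <- list(
    emb = emb,
    fwd_W = NULL, fwd_b = NULL, bwd_W = NULL, bwd_b = NULL,
    W_e = matrix(stats::runif(m * 2L * h, -config$init_scale,
                              config$init_scale), m, 2L * h),
    trans = matrix(0, m + 1L, m)
  )
  fwd <- lstm_init(d, h, config$init_scale)
  bwd <- lstm_init(d, h, config$init_scale)
  params$fwd_W <- fwd$W; params$fwd_b <- fwd$b
  params$bwd_W <- bwd$W; params$bwd_b <- bwd$b

  ids <- lapply(corpus, function(s) vocab_lookup(s$chars, vocab))
  golds <- lapply(corpus, function(s) unname(scheme$tag_index[s$tags]))

  opt <- adam_new(params)
  gstep <- 0L
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(corpus))
    tot <- 0
    for (si in ord) {
      res <- labeler_step(params, ids[[si]], golds[[si]], d, h, config)
      tot <- tot + res$loss
      grads <- clip_global_norm(res$grads, config$clip)
      lr_g <- lr_schedule(config$lr, config$decay_rate,
                          config$decay_steps, gstep)
      upd <- adam_step(params, grads, opt, lr_g)
      params <- upd$params
      opt <- upd$state
      params$emb[1L, ] <- 0  # PAD row stays frozen
      gstep <- gstep + 1L
    }
    loss_history[ep] <- tot / length(corpus)
    if (verbose) {
      message(sprintf("epoch %d  mean -loglik %.4f", ep, loss_history[ep]))
    }
  }

  structure(list(vocab = vocab, scheme = scheme, params = params,
                 config = config, loss_history = loss_history),
            class = "emrisk_labeler")
}

# One sentence: forward, loss, full backward. Returns loss + named grads.
labeler_step <- function(params, idx, gold, d, h, config) {
  x <- params$emb[idx, , drop = FALSE]
  lstm_params <- list(
    fwd = list(W = params$fwd_W, b = params$fwd_b, H = h, d = d),
    bwd = list(W = params$bwd_W, b = params$bwd_b, H = h, d = d)
  )
  fw <- bilstm_forward_cached(x, lstm_params)
  p <- emission_scores(fw$h, params$W_e)
  cg <- crf_loss_grad(p, params$trans, gold)
  da <- cg$d_emissions * (1 - p^2)
  d_we <- crossprod(da, fw$h)
  dh <- da %*% params$W_e
  bb <- bilstm_backward(dh, lstm_params, fw)
  grads <- list(
    fwd_W = bb$fwd$d_W, fwd_b = bb$fwd$d_b,
    bwd_W = bb$bwd$d_W, bwd_b = bb$bwd$d_b,
    W_e = d_we, trans = cg$d_trans
  )
  if (config$fine_tune_embeddings) {
    d_emb <- matrix(0, nrow(params$emb), d)
    agg <- rowsum(bb$d_x, group = idx)
    d_emb[as.integer(rownames(agg)), ] <- agg
    d_emb[1L, ] <- 0
    grads$emb <- d_emb
  }
  list(loss = cg$loss, grads = grads)
}

#' @export
print.emrisk_labeler <- function(x, ...) {
  cat("<emrisk_labeler> vocab", length(x$vocab$tokens), "chars,",
      length(x$scheme$tags), "tags, H =", x$config$hidden, "\n")
  if (length(x$loss_history)) {
    cat("  final mean -loglik:",
        round(x$loss_history[length(x$loss_history)], 4), "\n")
  }
  invisible(x)
}

#' Predict BIO tags for a sentence
#'
#' @param model a trained \code{emrisk_labeler}
#' @param sentence string or character vector
#' @return character vector of tag strings (Viterbi path)
#' @export
predict_tags <- function(model, sentence) {
  chars <- split_chars(sentence)
  if (length(chars) == 0L) return(character())
  idx <- vocab_lookup(chars, model$vocab)
  x <- model$params$emb[idx, , drop = FALSE]
  h <- model$config$hidden
  d <- ncol(model$params$emb)
  lstm_params <- list(
    fwd = list(W = model$params$fwd_W, b = model$params$fwd_b, H = h, d = d),
    bwd = list(W = model$params$bwd_W, b = model$params$bwd_b, H = h, d = d)
  )
  hs <- bilstm_encode(x, lstm_params)
  p <- emission_scores(hs, model$params$W_e)
  vit <- crf_viterbi(p, model$params$trans)
  model$scheme$tags[vit$path]
}

#' Extract risk-factor mentions from raw text
#'
#' Runs Viterbi decoding and converts the BIO tag path into mention spans.
#'
#' @param model a trained \code{emrisk_labeler}
#' @param text input string
#' @return list of [risk_factor_mention()]
#' @export
extract_mentions <- function(model, text) {
  chars <- split_chars(text)
  if (length(chars) == 0L) return(list())
  decode_mentions(chars, predict_tags(model, chars), model$scheme)
}

#' Decode BIO tags into mention spans
#'
#' Maximal B-led runs of a single composite code become mentions. An
#' \code{I-x} whose predecessor carries a different code (or is \code{O}) is
#' repaired to \code{B-x} before decoding — the repair rule preserves
#' recall relative to dropping such tags.
#'
#' @param sentence character vector (or string) the tags refer to
#' @param tags character vector of tag strings, same length
#' @param scheme a [tag_scheme()]
#' @return list of [risk_factor_mention()], in span order
#' @export
decode_mentions <- function(sentence, tags, scheme = tag_scheme()) {
  chars <- split_chars(sentence)
  if (length(chars) != length(tags)) {
    stop("sentence and tags differ in length")
  }
  validate_tags(tags, scheme)
  n <- length(tags)
  # repair orphan I- tags to B-
  fixed <- tags
  prev_code <- ""
  for (i in seq_len(n)) {
    tg <- fixed[[i]]
    if (startsWith(tg, "I-")) {
      code <- substring(tg, 3L)
      if (prev_code != code) fixed[[i]] <- paste0("B-", code)
    }
    prev_code <- if (tg == "O") "" else substring(tg, 3L)
  }
  mentions <- list()
  i <- 1L
  while (i <= n) {
    tg <- fixed[[i]]
    if (startsWith(tg, "B-")) {
      code <- substring(tg, 3L)
      j <- i + 1L
      while (j <= n && fixed[[j]] == paste0("I-", code)) j <- j + 1L
      parts <- split_code(code, scheme)
      mentions[[length(mentions) + 1L]] <- risk_factor_mention(
        parts$type, parts$temporal, i - 1L, j - 1L,
        paste(chars[i:(j - 1L)], collapse = "")
      )
      i <- j
    } else {
      i <- i + 1L
    }
  }
  mentions
}

#' Tags of a gold mention set
#'
#' Inverse of [decode_mentions()] for non-overlapping mentions: produces the
#' BIO tag sequence whose decoding recovers the mentions exactly.
#'
#' @param mentions list of [risk_factor_mention()], non-overlapping
#' @param n sentence length in characters
#' @param scheme a [tag_scheme()]
#' @return character vector of n tag strings
#' @export
mentions_to_tags <- function(mentions, n, scheme = tag_scheme()) {
  tags <- rep("O", n)
  for (m in mentions) {
    if (m$end > n) stop("mention span exceeds sentence length")
    code <- paste0(m$type, m$temporal)
    if (!code %in% scheme$codes) stop("unknown composite code: ", code)
    span <- (m$start + 1L):m$end
    if (any(tags[span] != "O")) stop("overlapping mentions")
    tags[span[1L]] <- paste0("B-", code)
    if (length(span) > 1L) tags[span[-1L]] <- paste0("I-", code)
  }
  tags
}
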