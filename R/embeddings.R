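#' Train character embeddings by skip-gram with negative sampling
#'
#' Trains distributed character vectors on a corpus of sentences, optionally
#' augmented with a dictionary of risk-factor surface strings. Each
#' dictionary entry is appended to the training stream \code{dict_times}
#' times as its own short sentence, so the characters of a risk factor
#' co-occur tightly and end up close in embedding space.
#'
#' The trainer is a plain single-threaded skip-gram with negative sampling:
#' for every (center, context) pair within \code{window}, one positive and
#' \code{negatives} noise targets (drawn from the unigram distribution
#' raised to 3/4) receive a logistic gradient step. The returned embedding
#' is the sum of the input and output (context) matrices, so that it
#' carries both paradigmatic (shared-context) and first-order
#' (co-occurrence) structure — the latter is what tight dictionary
#' co-occurrence trains. The \code{<PAD>} row is frozen at zero and never
#' trained. A fixed \code{seed} gives a bitwise reproducible matrix.
#'
#' @param corpus list of sentences (strings or character vectors)
#' @param dictionary character vector of risk-factor surface strings; OOV
#'   characters in the dictionary are added to the vocabulary
#' @param dim embedding dimension (default 100)
#' @param window symmetric context window (default 5)
#' @param negatives noise samples per positive (default 5)
#' @param epochs passes over the training stream (default 5)
#' @param seed RNG seed
#' @param dict_times how many times each dictionary entry is appended
#' @param lr learning rate (fixed; default 0.025)
#' @param min_count vocabulary frequency cutoff
#' @return list with \code{vocab} (a \code{char_vocab}) and \code{matrix}
#'   (v x dim, rownames = tokens, PAD row all zero)
#' @export
train_char_embeddings <- function(corpus, dictionary = character(),
                                  dim = 100L, window = 5L, negatives = 5L,
                                  epochs = 5L, seed = 1L, dict_times = 10L,
                                  lr = 0.025, min_count = 1L) {
  stopifnot(dim >= 1L, window >= 1L, negatives >= 0L, epochs >= 1L)
  stream <- c(corpus, rep(as.list(dictionary), each = dict_times))
  stream <- lapply(stream, split_chars)
  stream <- stream[lengths(stream) > 0L]
  if (length(stream) == 0L) {
    stop("nothing to train on: empty corpus and empty dictionary")
  }
  vocab <- build_vocab(stream, min_count = min_count)
  v <- length(vocab$tokens)
  ids <- lapply(stream, vocab_lookup, vocab = vocab)

  # noise distribution: unigram^(3/4) over real characters only
  counts <- numeric(v)
  tab <- table(unlist(ids, use.names = FALSE))
  counts[as.integer(names(tab))] <- as.numeric(tab)
  counts[1:2] <- 0
  noise <- counts^0.75
  noise <- noise / sum(noise)

  set.seed(as.integer(seed))
  w_in <- matrix(stats::runif(v * dim, -0.5, 0.5) / dim, nrow = v)
  w_out <- matrix(0, nrow = v, ncol = dim)
  w_in[1L, ] <- 0

  for (ep in seq_len(epochs)) {
    for (sent in ids) {
      n <- length(sent)
      for (t in seq_len(n)) {
        lo <- max(1L, t - window)
        hi <- min(n, t + window)
        ctx <- sent[setdiff(lo:hi, t)]
        if (length(ctx) == 0L) next
        w <- sent[[t]]
        for (c in ctx) {
          targets <- c(c, sample.int(v, negatives, replace = TRUE,
                                     prob = noise))
          labels <- c(1, numeric(negatives))
          vin <- w_in[w, ]
          outs <- w_out[targets, , drop = FALSE]
          g <- lr * (labels - 1 / (1 + exp(-drop(outs %*% vin))))
          w_in[w, ] <- vin + drop(crossprod(outs, g))
          w_out[targets, ] <- outs + outer(g, vin)
        }
      }
    }
  }
  mat <- w_in + w_out
  mat[1L, ] <- 0
  rownames(mat) <- vocab$tokens
  list(vocab = vocab, matrix = mat)
}

#' Cosine similarity between two embedding rows
#'
#' With \code{center = TRUE} the column means over real tokens (excluding
#' the frozen \code{<PAD>} row) are removed first, which strips the common
#' drift component all trained vectors share and makes the similarity
#' discriminative on small corpora.
#'
#' @param matrix embedding matrix with token rownames
#' @param a,b tokens
#' @param center subtract column means before comparing
#' @return cosine similarity in [-1, 1]
#' @export
embedding_cosine <- function(matrix, a, b, center = FALSE) {
  if (center) {
    real <- setdiff(rownames(matrix), "<PAD>")
    mu <- colMeans(matrix[real, , drop = FALSE])
    matrix <- sweep(matrix, 2L, mu)
  }
  x <- matrix[a, ]
  y <- matrix[b, ]
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
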