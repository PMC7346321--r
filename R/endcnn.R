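#' Configuration of the pyramid CNN classifier
#'
#' Defaults are the shared hyper-parameter table: region size \code{k} 7
#' (one packed unit), kernel size \code{ks} 3, pooling stride \code{s} 2,
#' \code{m} 250 feature maps throughout, depth \code{d_p} 15 weight layers
#' (1 region-embedding layer + 7 blocks x 2 convolution layers), learning
#' rate 0.001 decaying by 0.99 every 500 steps, batch size 64, keep rate
#' 0.5, 30 epochs.
#'
#' @param k region size (window of unit cells read by the first layer)
#' @param m number of feature maps, constant across all blocks
#' @param ks convolution kernel size
#' @param stride pooling stride
#' @param depth number of weight layers \code{d_p}; blocks = (depth - 1)/2
#' @param lr,decay_rate,decay_steps learning-rate schedule
#' @param batch minibatch size
#' @param keep_prob dropout keep rate
#' @param epochs training epochs
#' @param clip global gradient-norm ceiling
#' @param init_scale uniform init half-width
#' @param weight_decay decoupled L2 decay applied to weight matrices (not
#'   biases) at every update
#' @param permute_units during training, re-order each document's 7-cell
#'   units at every presentation. The unit sequence represents an
#'   unordered set of extracted risk factors, so the label is invariant
#'   under unit permutation; presenting fresh permutations prevents the
#'   network from memorizing particular unit orders and forces
#'   order-invariant features
#' @param l1_region lasso penalty on the region-embedding weights, applied
#'   proximally (soft-thresholding by \code{lr * l1_region} after each
#'   update). The one-hot region matrix has one column per (token, window
#'   offset); sparsity here makes the first layer read few informative
#'   tokens instead of memorizing surface combinations
#' @param class_weights \code{"balanced"} weights each document's loss
#'   inversely to its class frequency (n / (2 n_c)), \code{"none"} leaves
#'   the loss unweighted. With skewed prevalence the unweighted loss lets
#'   the minority-class decision boundary go uncalibrated
#' @param word_dropout probability of replacing an input token with
#'   \code{<UNK>} at each training presentation (0 disables; default 0.5).
#'   Word dropout makes memorizing particular token combinations
#'   unreliable and pushes the network toward features robust to missing
#'   tokens; with few training documents it is the strongest
#'   regularizer of the set
#' @return list of class \code{endcnn_config}
#' @export
endcnn_config <- function(k = 7L, m = 250L, ks = 3L, stride = 2L,
                          depth = 15L, lr = 0.001, decay_rate = 0.99,
                          decay_steps = 500L, batch = 64L, keep_prob = 0.5,
                          epochs = 30L, clip = 5.0, init_scale = 0.05,
                          weight_decay = 0, permute_units = TRUE,
                          l1_region = 0,
                          class_weights = c("none", "balanced"),
                          word_dropout = 0.5) {
  class_weights <- match.arg(class_weights)
  depth <- as.integer(depth)
  if ((depth - 1L) %% 2L != 0L || depth < 3L) {
    stop("depth must be 1 + 2 * (number of blocks), got ", depth)
  }
  structure(list(k = as.integer(k), m = as.integer(m), ks = as.integer(ks),
                 stride = as.integer(stride), depth = depth,
                 n_blocks = (depth - 1L) %/% 2L,
                 lr = lr, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 batch = as.integer(batch), keep_prob = keep_prob,
                 epochs = as.integer(epochs), clip = clip,
                 init_scale = init_scale, weight_decay = weight_decay,
                 permute_units = isTRUE(permute_units),
                 l1_region = l1_region, class_weights = class_weights,
                 word_dropout = word_dropout),
            class = "endcnn_config")
}

# Window offsets for a k-cell region: centered for odd k; for even k the
# window takes one more cell to the right (floor((k-1)/2) left, rest right).
region_offsets <- function(k) {
  lo <- (k - 1L) %/% 2L
  seq.int(-lo, k - 1L - lo)
}

#' Initialize a pyramid CNN model
#'
#' When pre-trained character embeddings are supplied, the region-embedding
#' weight columns of tokens found in the embedding vocabulary are
#' initialized as a seeded random projection of their embedding vectors
#' (one projection per window offset), so tokens with similar embeddings —
#' e.g. surface variants of the same risk factor after dictionary-injected
#' skip-gram training — produce similar region activations from the start.
#' The one-hot input contract is unchanged; only the starting point of W
#' moves. Tokens without an embedding row (label tokens, specials) keep the
#' uniform random init.
#'
#' @param config an [endcnn_config()]
#' @param unit_vocab a \code{unit_vocab} (defines the one-hot dimension v)
#' @param seed RNG seed
#' @param zero_blocks initialize every convolution block at zero, making
#'   each block the identity map (used by the identity-at-init checks)
#' @param embeddings optional pre-trained character embeddings: the list
#'   returned by [train_char_embeddings()], or a matrix with token rownames
#' @return object of class \code{endcnn_model}
#' @export
endcnn_init <- function(config, unit_vocab, seed = 1L,
                        zero_blocks = FALSE, embeddings = NULL) {
  set.seed(as.integer(seed))
  v <- length(unit_vocab$tokens)
  m <- config$m
  sc <- config$init_scale
  params <- list(
    region_W = matrix(stats::runif(m * config$k * v, -sc, sc), m),
    region_b = numeric(m),
    head_W = matrix(stats::runif(2L * m, -sc, sc), 2L, m),
    head_b = numeric(2L)
  )
  if (!is.null(embeddings)) {
    emat <- if (is.list(embeddings)) embeddings$matrix else embeddings
    known <- intersect(unit_vocab$tokens, rownames(emat))
    known <- setdiff(known, "<PAD>")
    d <- ncol(emat)
    for (j in seq_len(config$k)) {
      proj <- matrix(stats::rnorm(m * d, sd = 1 / sqrt(d)), m, d)
      cols <- (j - 1L) * v + unname(unit_vocab$index[known])
      params$region_W[, cols] <-
        proj %*% t(emat[known, , drop = FALSE]) * 0.4
    }
  }
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    mk <- function() {
      if (zero_blocks) matrix(0, m, config$ks * m)
      else matrix(stats::runif(m * config$ks * m, -sc, sc), m)
    }
    blocks[[b]] <- list(W1 = mk(), b1 = numeric(m),
                        W2 = mk(), b2 = numeric(m))
  }
  params$blocks <- blocks
  structure(list(config = config, unit_vocab = unit_vocab, params = params,
                 loss_history = numeric(0)),
            class = "endcnn_model")
}

#' @export
print.endcnn_model <- function(x, ...) {
  cat("<endcnn_model>", x$config$n_blocks, "blocks,", x$config$m,
      "feature maps, k =", x$config$k, ", vocab",
      length(x$unit_vocab$tokens), "\n")
  invisible(x)
}

#' Text region embedding
#'
#' Computes \eqn{W x + b} at every position, where \eqn{x} is the
#' kv-dimensional concatenation of the k one-hot vectors of the cells in
#' the window around the position (edges padded with \code{<PAD>}). No
#' nonlinearity here: activation is delayed to the pre-activation of the
#' next layer.
#'
#' @param units integer vector of token indices (length n >= 1)
#' @param w m x (k*v) weight matrix
#' @param b m-vector bias
#' @param k region size
#' @param v vocabulary size
#' @return m x n internal representation
#' @export
region_embed <- function(units, w, b, k, v) {
  n <- length(units)
  if (n < 1L) stop("empty unit sequence")
  if (ncol(w) != k * v) {
    stop("region weight matrix has ", ncol(w), " columns, expected k*v = ",
         k * v)
  }
  offs <- region_offsets(k)
  out <- matrix(b, nrow(w), n)
  for (j in seq_len(k)) {
    pos <- seq_len(n) + offs[[j]]
    idx <- ifelse(pos >= 1L & pos <= n, units[pmin(pmax(pos, 1L), n)], 1L)
    out <- out + w[, (j - 1L) * v + idx, drop = FALSE]
  }
  out
}

# stack ks=3 shifted copies of a (m x n) into (3m x n), zero padded
stack3 <- function(a) {
  n <- ncol(a)
  m <- nrow(a)
  left <- cbind(matrix(0, m, 1L), a[, seq_len(n - 1L), drop = FALSE])
  right <- cbind(a[, seq.int(2L, length.out = n - 1L), drop = FALSE],
                 matrix(0, m, 1L))
  rbind(left, a, right)
}

# adjoint of stack3: collapse a (3m x n) gradient back to (m x n)
unstack3 <- function(g, m) {
  n <- ncol(g)
  top <- g[seq_len(m), , drop = FALSE]
  mid <- g[m + seq_len(m), , drop = FALSE]
  bot <- g[2L * m + seq_len(m), , drop = FALSE]
  da_top <- cbind(top[, seq.int(2L, length.out = n - 1L), drop = FALSE],
                  matrix(0, m, 1L))
  da_bot <- cbind(matrix(0, m, 1L),
                  bot[, seq_len(n - 1L), drop = FALSE])
  da_top + mid + da_bot
}

#' Pre-activation convolution layer
#'
#' Computes \eqn{W \sigma(x) + b} at every position with
#' \eqn{\sigma(x) = max(x, 0)}: the rectifier is applied to the input
#' BEFORE the linear weighting. Same-length convolution with zero padding,
#' kernel size 3.
#'
#' @param rep m x n internal representation
#' @param w m x 3m weight matrix
#' @param b m-vector bias
#' @return m x n representation
#' @export
conv_preact <- function(rep, w, b) {
  m <- nrow(rep)
  if (ncol(w) != 3L * m) {
    stop("conv weight matrix has ", ncol(w), " columns for width ", m)
  }
  w %*% stack3(pmax(rep, 0)) + b
}

#' Pre-activation convolution block with identity shortcut
#'
#' \eqn{z + f(z)} where f is two pre-activation convolution layers. Both
#' layers preserve width and length, so the shortcut is exact identity —
#' no dimension matching anywhere.
#'
#' @param rep m x n representation
#' @param block list with \code{W1}, \code{b1}, \code{W2}, \code{b2}
#' @return m x n representation, same shape as the input
#' @export
conv_block <- function(rep, block) {
  rep + conv_preact(conv_preact(rep, block$W1, block$b1),
                    block$W2, block$b2)
}

#' Max-pool downsampling (size 3, stride 2)
#'
#' Componentwise maximum over size-3 windows centered at every other
#' position, with \eqn{-\infty} padding at the ends, so the output length
#' is exactly \code{ceiling(n / 2)}: each downsampling halves the internal
#' representation.
#'
#' @param rep m x n representation
#' @return m x ceiling(n/2) representation
#' @export
downsample <- function(rep) {
  pool_cached(rep)$out
}

# pooling with argmax cache for backprop: output column i takes the max
# over input columns (2i-2, 2i-1, 2i), 1-based, out-of-range = -Inf
pool_cached <- function(rep) {
  n <- ncol(rep)
  m <- nrow(rep)
  n_out <- ceiling(n / 2)
  out <- matrix(-Inf, m, n_out)
  arg <- matrix(0L, m, n_out)
  for (i in seq_len(n_out)) {
    cols <- (2L * i - 2L):(2L * i)
    cols <- cols[cols >= 1L & cols <= n]
    sub <- rep[, cols, drop = FALSE]
    j <- max.col(sub, ties.method = "first")
    out[, i] <- sub[cbind(seq_len(m), j)]
    arg[, i] <- cols[j]
  }
  list(out = out, arg = arg)
}

#' Global max pooling
#'
#' Aggregates the internal representation of a document into one m-vector
#' by componentwise maximum over all positions.
#'
#' @param rep m x n representation (n >= 1)
#' @return m-vector
#' @export
final_pool <- function(rep) {
  j <- max.col(rep, ties.method = "first")
  rep[cbind(seq_len(nrow(rep)), j)]
}

# whether to insert a pooling layer at current length: stop once the
# output would drop below 2 positions
pool_ok <- function(n) ceiling(n / 2) >= 2L

#' Forward pass of the pyramid CNN
#'
#' region embedding -> block -> [pool -> block] x (blocks - 1) ->
#' global max pool -> linear head -> normalized exponential. Pool layers
#' stop being inserted once the representation would drop below 2
#' positions; remaining blocks run at the floor length.
#'
#' @param units integer vector of unit-token indices (non-empty)
#' @param model an \code{endcnn_model}
#' @return length-2 probability vector (no-CVD, CVD), summing to 1
#' @export
endcnn_forward <- function(units, model) {
  if (length(units) == 0L) stop("empty unit sequence")
  p <- model$params
  cfg <- model$config
  rep <- region_embed(units, p$region_W, p$region_b, cfg$k,
                      length(model$unit_vocab$tokens))
  rep <- conv_block(rep, p$blocks[[1L]])
  for (b in seq_len(cfg$n_blocks)[-1L]) {
    if (pool_ok(ncol(rep))) rep <- downsample(rep)
    rep <- conv_block(rep, p$blocks[[b]])
  }
  vec <- final_pool(rep)
  scores <- drop(p$head_W %*% vec) + p$head_b
  scores <- scores - max(scores)
  e <- exp(scores)
  unname(e / sum(e))
}

# ---- training path: forward with caches, and full backward ----

endcnn_forward_train <- function(units, params, cfg, v, keep_prob) {
  rep <- region_embed(units, params$region_W, params$region_b, cfg$k, v)
  # dropout is applied to the final pooled vector only: deleting one-hot
  # evidence after the region embedding measurably hurt held-out accuracy
  # at small m (see the methods vignette)
  mask0 <- 1
  caches <- vector("list", cfg$n_blocks)
  pools <- vector("list", cfg$n_blocks)
  block_fwd <- function(z, blk) {
    a1 <- pmax(z, 0)
    x1 <- stack3(a1)
    u1 <- blk$W1 %*% x1 + blk$b1
    a2 <- pmax(u1, 0)
    x2 <- stack3(a2)
    u2 <- blk$W2 %*% x2 + blk$b2
    list(out = z + u2, z = z, x1 = x1, u1 = u1, x2 = x2)
  }
  cc <- block_fwd(rep, params$blocks[[1L]])
  caches[[1L]] <- cc
  rep <- cc$out
  for (b in seq_len(cfg$n_blocks)[-1L]) {
    if (pool_ok(ncol(rep))) {
      pc <- pool_cached(rep)
      pools[[b]] <- pc
      rep <- pc$out
    }
    cc <- block_fwd(rep, params$blocks[[b]])
    caches[[b]] <- cc
    rep <- cc$out
  }
  jmax <- max.col(rep, ties.method = "first")
  vec <- rep[cbind(seq_len(nrow(rep)), jmax)]
  mask1 <- (stats::runif(length(vec)) < keep_prob) / keep_prob
  vecd <- vec * mask1
  scores <- drop(params$head_W %*% vecd) + params$head_b
  scores <- scores - max(scores)
  e <- exp(scores)
  probs <- e / sum(e)
  list(probs = probs, caches = caches, pools = pools, jmax = jmax,
       vecd = vecd, mask0 = mask0, mask1 = mask1,
       final_len = ncol(rep), units = units)
}

endcnn_backward <- function(fw, label, params, cfg, v) {
  m <- cfg$m
  target <- c(1 - label, label)
  dscores <- fw$probs - target
  g <- list(head_W = outer(dscores, fw$vecd), head_b = dscores)
  dvecd <- drop(crossprod(params$head_W, dscores))
  dvec <- dvecd * fw$mask1
  drep <- matrix(0, m, fw$final_len)
  drep[cbind(seq_len(m), fw$jmax)] <- dvec

  block_bwd <- function(dy, blk, cc) {
    du2 <- dy
    d_w2 <- tcrossprod(du2, cc$x2)
    d_b2 <- rowSums(du2)
    dx2 <- crossprod(blk$W2, du2)
    da2 <- unstack3(dx2, m)
    du1 <- da2 * (cc$u1 > 0)
    d_w1 <- tcrossprod(du1, cc$x1)
    d_b1 <- rowSums(du1)
    dx1 <- crossprod(blk$W1, du1)
    da1 <- unstack3(dx1, m)
    dz <- dy + da1 * (cc$z > 0)
    list(dz = dz, grads = list(W1 = d_w1, b1 = d_b1, W2 = d_w2, b2 = d_b2))
  }

  gblocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bb <- block_bwd(drep, params$blocks[[b]], fw$caches[[b]])
    gblocks[[b]] <- bb$grads
    drep <- bb$dz
    if (b > 1L && !is.null(fw$pools[[b]])) {
      pc <- fw$pools[[b]]
      n_in <- max(pc$arg)
      up <- matrix(0, m, ncol(fw$caches[[b - 1L]]$z))
      # route each pooled gradient back to its argmax column
      for (i in seq_len(ncol(drep))) {
        ii <- cbind(seq_len(m), pc$arg[, i])
        up[ii] <- up[ii] + drep[, i]
      }
      drep <- up
    }
  }
  g$blocks <- gblocks

  drep0 <- drep * fw$mask0
  g$region_b <- rowSums(drep0)
  d_w <- matrix(0, m, cfg$k * v)
  offs <- region_offsets(cfg$k)
  n <- length(fw$units)
  for (j in seq_len(cfg$k)) {
    pos <- seq_len(n) + offs[[j]]
    idx <- ifelse(pos >= 1L & pos <= n, fw$units[pmin(pmax(pos, 1L), n)], 1L)
    agg <- rowsum(t(drep0), group = idx)
    cols <- (j - 1L) * v + as.integer(rownames(agg))
    d_w[, cols] <- d_w[, cols] + t(agg)
  }
  g$region_W <- d_w
  g
}

#' Train the pyramid CNN classifier
#'
#' Minibatch Adam on the cross-entropy of the softmax head, with dropout
#' (keep rate \code{keep_prob}) after the region embedding and on the final
#' pooled vector, the exponential learning-rate schedule, and global
#' gradient-norm clipping. Seed-deterministic on a single thread.
#'
#' @param dataset list of records, each with \code{units} (integer vector)
#'   and \code{label} (0/1)
#' @param unit_vocab the \code{unit_vocab} the units are indexed against
#' @param config an [endcnn_config()]
#' @param seed RNG seed
#' @param embeddings optional pre-trained character embeddings used to
#'   initialize the region-embedding weights (see [endcnn_init()])
#' @param verbose print per-epoch mean loss
#' @return a trained \code{endcnn_model} with \code{loss_history}
#' @export
train_classifier <- function(dataset, unit_vocab,
                             config = endcnn_config(), seed = 1L,
                             embeddings = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  labels <- vapply(dataset, `[[`, numeric(1), "label")
  if (length(unique(labels)) < 2L) {
    warning("dataset contains a single class; training anyway")
  }
  model <- endcnn_init(config, unit_vocab, seed = seed,
                       embeddings = embeddings)
  v <- length(unit_vocab$tokens)
  cw <- c(1, 1)
  if (config$class_weights == "balanced") {
    n_neg <- sum(labels == 0)
    n_pos <- sum(labels == 1)
    if (n_neg > 0L && n_pos > 0L) {
      cw <- length(labels) / (2 * c(n_neg, n_pos))
    }
  }
  flat <- flatten_params(model$params)
  opt <- adam_new(flat)
  gstep <- 0L
  loss_history <- numeric(config$epochs)
  n <- length(dataset)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq.int(1L, n, by = config$batch)) {
      batch <- ord[seq.int(start, min(start + config$batch - 1L, n))]
      acc <- NULL
      for (di in batch) {
        rec <- dataset[[di]]
        u <- rec$units
        if (config$permute_units) u <- permute_unit_cells(u)
        if (config$word_dropout > 0) {
          drop_mask <- stats::runif(length(u)) < config$word_dropout
          u[drop_mask & u != 1L] <- 2L  # <PAD> cells stay
        }
        fw <- endcnn_forward_train(u, model$params, config, v,
                                   config$keep_prob)
        wgt <- cw[rec$label + 1L]
        tot <- tot - wgt * log(max(fw$probs[rec$label + 1L], 1e-12))
        g <- endcnn_backward(fw, rec$label, model$params, config, v)
        gf <- lapply(flatten_params(g), function(x) x * wgt)
        acc <- if (is.null(acc)) gf else Map(`+`, acc, gf)
      }
      acc <- lapply(acc, function(x) x / length(batch))
      acc <- clip_global_norm(acc, config$clip)
      lr_g <- lr_schedule(config$lr, config$decay_rate, config$decay_steps,
                          gstep)
      upd <- adam_step(flat, acc, opt, lr_g)
      flat <- upd$params
      opt <- upd$state
      if (config$weight_decay > 0) {
        wnames <- grep("_W$|_W[12]$|^region_W$|^head_W$", names(flat),
                       value = TRUE)
        for (nm in wnames) {
          flat[[nm]] <- flat[[nm]] * (1 - lr_g * config$weight_decay)
        }
      }
      if (config$l1_region > 0) {
        thr <- lr_g * config$l1_region
        w <- flat$region_W
        flat$region_W <- sign(w) * pmax(abs(w) - thr, 0)
      }
      model$params <- unflatten_params(flat, config)
      gstep <- gstep + 1L
    }
    loss_history[ep] <- tot / n
    if (verbose) {
      message(sprintf("epoch %d  mean CE loss %.4f", ep, loss_history[ep]))
    }
  }
  model$loss_history <- loss_history
  model
}

# randomly re-order the 7-cell units of a packed sequence (training
# augmentation; the label is invariant under unit permutation)
permute_unit_cells <- function(units, cell_width = 7L) {
  nu <- length(units) %/% cell_width
  if (nu < 2L) return(units)
  ord <- sample.int(nu)
  idx <- rep((ord - 1L) * cell_width, each = cell_width) +
    seq_len(cell_width)
  units[idx]
}

flatten_params <- function(p) {
  out <- list(region_W = p$region_W, region_b = p$region_b,
              head_W = p$head_W, head_b = p$head_b)
  for (b in seq_along(p$blocks)) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      out[[paste0("blk", b, "_", nm)]] <- p$blocks[[b]][[nm]]
    }
  }
  out
}

unflatten_params <- function(flat, cfg) {
  p <- list(region_W = flat$region_W, region_b = flat$region_b,
            head_W = flat$head_W, head_b = flat$head_b)
  blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    blocks[[b]] <- list(W1 = flat[[paste0("blk", b, "_W1")]],
                        b1 = flat[[paste0("blk", b, "_b1")]],
                        W2 = flat[[paste0("blk", b, "_W2")]],
                        b2 = flat[[paste0("blk", b, "_b2")]])
  }
  p$blocks <- blocks
  p
}

#' Analytic multiply-accumulate counts per block
#'
#' With the number of feature maps fixed, the block at level \eqn{\ell}
#' (0-based) processes \code{ceiling(doc_length / 2^l)} positions at
#' \code{2 * ks * m^2} MACs per position, so every stride-2 downsampling
#' halves the per-block computation and the total stays bounded by about
#' twice the first block's cost.
#'
#' @param config an [endcnn_config()]
#' @param doc_length input length in unit cells (>= 1)
#' @return numeric vector of per-block MAC counts, one per block
#' @export
count_macs <- function(config, doc_length) {
  stopifnot(doc_length >= 1)
  per_pos <- 2 * config$ks * as.numeric(config$m)^2
  lev <- seq_len(config$n_blocks) - 1L
  ceiling(doc_length / 2^lev) * per_pos
}

#' Receptive field after L downsamplings
#'
#' Exact recurrence on the original-document coverage r and the cumulative
#' stride (jump) j: r starts at the region size k with j = 1; each
#' convolution layer adds (ks - 1) * j, each pooling adds (3 - 1) * j and
#' then doubles j. The network runs one block, then L pool+block stages.
#' After L pools the jump is 2^L and r grows like 2^L — long-range
#' associations in the order of 2^L positions become representable.
#'
#' @param config an [endcnn_config()]
#' @param L number of downsampling stages (>= 0)
#' @return list with \code{r} (covered positions in the original document)
#'   and \code{jump} (cumulative stride, = 2^L)
#' @export
receptive_field <- function(config, L) {
  stopifnot(L >= 0)
  r <- as.numeric(config$k)
  j <- 1
  conv_add <- 2 * (config$ks - 1)  # two conv layers per block
  r <- r + conv_add * j
  for (l in seq_len(L)) {
    r <- r + 2 * j  # size-3 pool widens by (3 - 1) * j
    j <- 2 * j
    r <- r + conv_add * j
  }
  list(r = r, jump = j)
}
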