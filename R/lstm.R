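#' LSTM parameters for one direction
#'
#' Standard LSTM cell with input, forget and output gates and a tanh
#' candidate, no peepholes:
#' \deqn{i,f,o = sigmoid, \quad g = tanh, \quad c_t = f c_{t-1} + i g,
#'       \quad h_t = o \tanh(c_t).}
#' Weights are stored as one 4H x (d + H) matrix over the concatenated
#' \code{[x_t; h_{t-1}]}, gate order i, f, o, g, plus a 4H bias. The forget
#' gate bias is initialized to 1 so early training does not erase state.
#'
#' @param input_dim embedding dimension d
#' @param hidden_dim hidden size H
#' @param init_scale uniform init half-width; 0 gives all-zero parameters
#' @return list with \code{W} (4H x (d+H)), \code{b} (4H), \code{H}, \code{d}
#' @keywords internal
lstm_init <- function(input_dim, hidden_dim, init_scale = 0.08) {
  w <- matrix(stats::runif(4L * hidden_dim * (input_dim + hidden_dim),
                           -init_scale, init_scale),
              nrow = 4L * hidden_dim)
  b <- numeric(4L * hidden_dim)
  b[hidden_dim + seq_len(hidden_dim)] <- 1  # forget gate bias
  list(W = w, b = b, H = hidden_dim, d = input_dim)
}

# One-direction forward pass with cache for backpropagation through time.
# x: n x d. Returns h (n x H) plus cached activations.
lstm_forward <- function(x, params) {
  h_dim <- params$H
  d <- params$d
  n <- nrow(x)
  if (ncol(x) != d) stop("input is ", ncol(x), "-dimensional, expected ", d)
  hs <- matrix(0, n, h_dim)
  if (n == 0L) {
    return(list(h = hs, cache = NULL))
  }
  wx <- params$W[, seq_len(d), drop = FALSE]
  wh <- params$W[, d + seq_len(h_dim), drop = FALSE]
  zx <- x %*% t(wx)  # n x 4H, input contribution precomputed
  idx_i <- seq_len(h_dim)
  idx_f <- h_dim + idx_i
  idx_o <- 2L * h_dim + idx_i
  idx_g <- 3L * h_dim + idx_i
  gates <- matrix(0, n, 4L * h_dim)
  cs <- matrix(0, n, h_dim)
  tanhc <- matrix(0, n, h_dim)
  h_prev <- numeric(h_dim)
  c_prev <- numeric(h_dim)
  for (t in seq_len(n)) {
    z <- zx[t, ] + drop(wh %*% h_prev) + params$b
    gi <- 1 / (1 + exp(-z[idx_i]))
    gf <- 1 / (1 + exp(-z[idx_f]))
    go <- 1 / (1 + exp(-z[idx_o]))
    gg <- tanh(z[idx_g])
    c_t <- gf * c_prev + gi * gg
    tc <- tanh(c_t)
    h_t <- go * tc
    gates[t, ] <- c(gi, gf, go, gg)
    cs[t, ] <- c_t
    tanhc[t, ] <- tc
    hs[t, ] <- h_t
    h_prev <- h_t
    c_prev <- c_t
  }
  list(h = hs,
       cache = list(x = x, gates = gates, cs = cs, tanhc = tanhc, hs = hs,
                    wx = wx, wh = wh))
}

# Backward pass for one direction. dh: n x H upstream gradient on the
# hidden outputs. Returns gradients for W, b and the inputs x.
lstm_backward <- function(dh, params, cache) {
  h_dim <- params$H
  d <- params$d
  n <- nrow(dh)
  if (n == 0L) {
    return(list(d_W = matrix(0, 4L * h_dim, d + h_dim),
                d_b = numeric(4L * h_dim), d_x = matrix(0, 0L, d)))
  }
  dz_all <- matrix(0, n, 4L * h_dim)
  idx_i <- seq_len(h_dim)
  idx_f <- h_dim + idx_i
  idx_o <- 2L * h_dim + idx_i
  idx_g <- 3L * h_dim + idx_i
  dc_next <- numeric(h_dim)
  dh_carry <- numeric(h_dim)
  t_wh <- t(cache$wh)
  for (t in n:1) {
    g <- cache$gates[t, ]
    gi <- g[idx_i]; gf <- g[idx_f]; go <- g[idx_o]; gg <- g[idx_g]
    tc <- cache$tanhc[t, ]
    c_prev <- if (t > 1L) cache$cs[t - 1L, ] else numeric(h_dim)
    dht <- dh[t, ] + dh_carry
    dc <- dht * go * (1 - tc^2) + dc_next
    dz <- numeric(4L * h_dim)
    dz[idx_i] <- dc * gg * gi * (1 - gi)
    dz[idx_f] <- dc * c_prev * gf * (1 - gf)
    dz[idx_o] <- dht * tc * go * (1 - go)
    dz[idx_g] <- dc * gi * (1 - gg^2)
    dz_all[t, ] <- dz
    dc_next <- dc * gf
    dh_carry <- drop(t_wh %*% dz)
  }
  h_prevs <- rbind(numeric(h_dim),
                   cache$hs[-n, , drop = FALSE])  # h_{t-1} rows
  d_w <- cbind(crossprod(dz_all, cache$x), crossprod(dz_all, h_prevs))
  list(d_W = d_w, d_b = colSums(dz_all), d_x = dz_all %*% cache$wx)
}

#' Encode a sentence with a bidirectional LSTM
#'
#' A forward LSTM reads the embedded sentence left to right and a backward
#' LSTM (with its own parameters) reads it right to left; the per-character
#' representation is the concatenation \code{[forward; backward]}, an
#' n x 2H matrix. Reversing the input and swapping the direction parameters
#' swaps the two halves of every row.
#'
#' @param x n x d matrix of character embeddings
#' @param params list with elements \code{fwd} and \code{bwd}, each from
#'   \code{lstm_init()}
#' @return n x 2H matrix of hidden states
#' @export
bilstm_encode <- function(x, params) {
  f <- lstm_forward(x, params$fwd)
  rev_idx <- rev(seq_len(nrow(x)))
  b <- lstm_forward(x[rev_idx, , drop = FALSE], params$bwd)
  cbind(f$h, b$h[rev_idx, , drop = FALSE])
}

# Forward with caches kept (training path).
bilstm_forward_cached <- function(x, params) {
  f <- lstm_forward(x, params$fwd)
  rev_idx <- rev(seq_len(nrow(x)))
  b <- lstm_forward(x[rev_idx, , drop = FALSE], params$bwd)
  list(h = cbind(f$h, b$h[rev_idx, , drop = FALSE]),
       fwd = f, bwd = b, rev_idx = rev_idx)
}

# Backward through both directions. dh: n x 2H. Returns per-direction
# parameter grads and the gradient on the embedded inputs.
bilstm_backward <- function(dh, params, fw) {
  h_dim <- params$fwd$H
  n <- nrow(dh)
  gf <- lstm_backward(dh[, seq_len(h_dim), drop = FALSE],
                      params$fwd, fw$fwd$cache)
  db_rev <- dh[fw$rev_idx, h_dim + seq_len(h_dim), drop = FALSE]
  gb <- lstm_backward(db_rev, params$bwd, fw$bwd$cache)
  d_x <- gf$d_x + gb$d_x[fw$rev_idx, , drop = FALSE]
  list(fwd = gf, bwd = gb, d_x = d_x)
}
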