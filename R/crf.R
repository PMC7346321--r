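#' Linear-chain CRF: exact inference
#'
#' The tagging layer scores a tag path y = (y_1, ..., y_n) for a sentence of
#' length n as the sum of transition scores and emission scores,
#' \deqn{s(X, y) = \sum_{i=1}^{n} (T_{y_{i-1}, y_i} + P_{i, y_i}),}
#' where \eqn{P} is the n x m emission matrix produced by the network,
#' \eqn{T} holds transition scores between successive tags and \eqn{y_0} is
#' a distinguished start state whose outgoing scores form the start row.
#' Normalizing \eqn{e^{s(X,y)}} over all \eqn{m^n} paths gives the path
#' probability; the log-normalizer is computed by the forward recursion in
#' log space, and the best path by the Viterbi algorithm.
#'
#' Throughout, \code{trans} is an (m+1) x m matrix: row 1 is the start row
#' (scores for the first tag), row i+1 holds transitions from tag i.
#'
#' @name crf
NULL

check_crf_dims <- function(emissions, trans) {
  m <- ncol(emissions)
  if (!is.matrix(trans) || nrow(trans) != m + 1L || ncol(trans) != m) {
    stop("transition matrix must be (m+1) x m with the start row first; ",
         "got ", nrow(trans), " x ", ncol(trans), " for m = ", m)
  }
  invisible(m)
}

#' Score one tag path
#'
#' @param emissions n x m emission score matrix (n >= 1)
#' @param trans (m+1) x m transition matrix, start row first
#' @param path integer vector of tag indices in 1..m, length n
#' @return the scalar path score
#' @rdname crf
#' @export
crf_path_score <- function(emissions, trans, path) {
  m <- check_crf_dims(emissions, trans)
  n <- nrow(emissions)
  if (length(path) != n || n < 1L) {
    stop("path length must equal nrow(emissions) >= 1")
  }
  if (any(path < 1L | path > m)) stop("tag index out of range 1..", m)
  from <- c(0L, path[-n]) + 1L  # start state occupies row 1
  sum(trans[cbind(from, path)]) + sum(emissions[cbind(seq_len(n), path)])
}

#' Log-partition function (forward algorithm, log space)
#'
#' @return log of the sum of exp path scores over all m^n paths
#' @rdname crf
#' @export
crf_log_partition <- function(emissions, trans) {
  m <- check_crf_dims(emissions, trans)
  n <- nrow(emissions)
  if (n < 1L) stop("empty sentence: the partition function needs n >= 1")
  alpha <- trans[1L, ] + emissions[1L, ]
  if (n > 1L) {
    body <- trans[-1L, , drop = FALSE]
    for (t in 2:n) {
      # alpha recycles down the columns of body: entry (i, j) scores
      # arriving in tag j from tag i
      scores <- alpha + body
      alpha <- log_col_sum_exp(scores) + emissions[t, ]
    }
  }
  log_sum_exp(alpha)
}

#' Log-likelihood of a tag path
#'
#' \code{crf_path_score} minus \code{crf_log_partition}; always <= 0, and
#' its exp is the path's conditional probability.
#'
#' @rdname crf
#' @export
crf_log_likelihood <- function(emissions, trans, path) {
  crf_path_score(emissions, trans, path) - crf_log_partition(emissions, trans)
}

#' Viterbi decoding
#'
#' Returns the maximum-score path and its score. Ties at each backpointer
#' are broken toward the lowest tag index, making decoding deterministic.
#'
#' @return list with \code{path} (integer vector) and \code{score}
#' @rdname crf
#' @export
crf_viterbi <- function(emissions, trans) {
  m <- check_crf_dims(emissions, trans)
  n <- nrow(emissions)
  if (n < 1L) stop("empty sentence: nothing to decode")
  delta <- trans[1L, ] + emissions[1L, ]
  back <- matrix(0L, nrow = n, ncol = m)
  if (n > 1L) {
    body <- trans[-1L, , drop = FALSE]
    for (t in 2:n) {
      scores <- delta + body
      # max.col with ties.method "first" = lowest predecessor index
      best <- max.col(t(scores), ties.method = "first")
      back[t, ] <- best
      delta <- scores[cbind(best, seq_len(m))] + emissions[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)  # which.max takes the first (lowest) maximum
  if (n > 1L) {
    for (t in n:2) path[t - 1L] <- back[t, path[t]]
  }
  list(path = path, score = unname(delta[path[n]]))
}

#' CRF loss and gradients for one sentence
#'
#' Negative log-likelihood of the gold path and its exact gradients with
#' respect to the emission and transition scores, via the forward-backward
#' marginals: d(-ll)/dP = posterior tag marginals minus the gold one-hot;
#' d(-ll)/dT = expected transition counts minus observed ones.
#'
#' @param emissions n x m emission matrix
#' @param trans (m+1) x m transition matrix
#' @param path gold tag indices
#' @return list with \code{loss}, \code{d_emissions} (n x m),
#'   \code{d_trans} ((m+1) x m)
#' @keywords internal
crf_loss_grad <- function(emissions, trans, path) {
  m <- check_crf_dims(emissions, trans)
  n <- nrow(emissions)
  body <- trans[-1L, , drop = FALSE]

  # scaled forward-backward (HMM-style rescaling): one matrix-vector
  # product per position instead of a log-sum-exp over an m x m matrix.
  # Safe here because emissions are tanh-bounded and transitions stay
  # moderate under gradient clipping; the exported crf_log_partition
  # keeps the fully general log-space recursion.
  expb <- exp(body)
  expe <- exp(emissions)
  a <- matrix(0, n, m)    # normalized forward after emission at t
  cs <- numeric(n)        # per-step normalizers; logZ = sum(log(cs))
  w <- exp(trans[1L, ]) * expe[1L, ]
  cs[1L] <- sum(w)
  a[1L, ] <- w / cs[1L]
  if (n > 1L) {
    for (t in 2:n) {
      w <- drop(a[t - 1L, ] %*% expb) * expe[t, ]
      cs[t] <- sum(w)
      a[t, ] <- w / cs[t]
    }
  }
  logz <- sum(log(cs))

  b <- matrix(0, n, m)    # scaled backward
  b[n, ] <- 1
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      b[t, ] <- drop(expb %*% (b[t + 1L, ] * expe[t + 1L, ])) / cs[t + 1L]
    }
  }

  marg <- a * b  # posterior tag marginals, rows sum to 1

  d_trans <- matrix(0, m + 1L, m)
  d_trans[1L, ] <- exp(trans[1L, ]) * expe[1L, ] * b[1L, ] / cs[1L]
  if (n > 1L) {
    # summed pairwise marginals factorize through exp(T):
    # xi_t[i,j] = a[t-1,i] expT[i,j] expP[t,j] b[t,j] / c_t
    u <- a[-n, , drop = FALSE]
    v <- expe[-1L, , drop = FALSE] * b[-1L, , drop = FALSE] / cs[-1L]
    d_trans[-1L, ] <- expb * crossprod(u, v)
  }

  # subtract observed gold counts
  d_emissions <- marg
  d_emissions[cbind(seq_len(n), path)] <-
    d_emissions[cbind(seq_len(n), path)] - 1
  from <- c(0L, path[-n]) + 1L
  # a gold transition may repeat; subtract its full count
  flat <- from + (path - 1L) * (m + 1L)
  cnt <- tabulate(flat, nbins = (m + 1L) * m)
  d_trans <- d_trans - matrix(cnt, m + 1L, m)

  loss <- logz - crf_path_score(emissions, trans, path)
  list(loss = loss, d_emissions = d_emissions, d_trans = d_trans)
}

# ---- numerically stable log-sum-exp helpers ----

log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# column-wise LSE of a matrix (max.col is much faster than apply)
log_col_sum_exp <- function(x) {
  mx <- x[cbind(max.col(t(x), ties.method = "first"), seq_len(ncol(x)))]
  mx + log(.colSums(exp(x - rep(mx, each = nrow(x))),
                    nrow(x), ncol(x)))
}

# row-wise LSE of a matrix
log_row_sum_exp <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  mx + log(.rowSums(exp(x - mx), nrow(x), ncol(x)))
}
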