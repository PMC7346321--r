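test_that("region embedding computes Wx+b over one-hot windows", {
  uv <- build_unit_vocab("abcd")
  v <- length(uv$tokens)

  # k = 1, b = 0: pure one-hot column selection
  set.seed(31)
  w <- matrix(stats::rnorm(3 * v), 3, v)
  u <- vocab_lookup(c("b", "d"), uv)
  expect_equal(region_embed(u, w, numeric(3), 1L, v), w[, u],
               tolerance = 1e-12)

  # k = 3 hand computation on a 5-token input with PAD at the edges
  k <- 3L
  w3 <- matrix(stats::rnorm(2 * k * v), 2, k * v)
  b <- c(0.5, -0.5)
  u <- vocab_lookup(c("a", "b", "c", "d", "a"), uv)
  got <- region_embed(u, w3, b, k, v)
  upad <- c(1L, u, 1L)
  for (t in 1:5) {
    win <- upad[t:(t + 2)]
    expect_equal(got[, t],
                 b + w3[, win[1]] + w3[, v + win[2]] + w3[, 2 * v + win[3]],
                 tolerance = 1e-12)
  }
  # input dimension is k*v: mismatched W is an error
  expect_error(region_embed(u, w3, b, 7L, v), "k\\*v")
  # region size 7 means the one-hot input is 7v-dimensional
  w7 <- matrix(0, 2, 7L * v)
  expect_silent(region_embed(u, w7, numeric(2), 7L, v))
})

test_that("pre-activation convolution rectifies before weighting", {
  set.seed(32)
  m <- 3L
  w <- matrix(stats::rnorm(m * 3 * m), m, 3 * m)
  b <- stats::rnorm(m)
  # W = 0 -> every column equals b
  rep0 <- matrix(stats::rnorm(m * 4), m, 4)
  expect_equal(conv_preact(rep0, w * 0, b),
               matrix(b, m, 4), tolerance = 1e-12)
  # all-negative input, b = 0 -> rectifier kills everything
  expect_true(all(conv_preact(-abs(rep0), w, numeric(m)) == 0))
  # single position, m = 1: scalar W sigma(x) + b with zero-padded window
  w1 <- matrix(c(2, 3, 4), 1, 3)
  x <- matrix(0.5, 1, 1)
  expect_equal(conv_preact(x, w1, 1)[1, 1], 3 * 0.5 + 1, tolerance = 1e-12)
  expect_error(conv_preact(rep0, matrix(0, m, 3 * m + 1), b), "columns")
})

test_that("convolution blocks are identity at zero and shape-preserving", {
  set.seed(33)
  m <- 4L
  zero_blk <- list(W1 = matrix(0, m, 3 * m), b1 = numeric(m),
                   W2 = matrix(0, m, 3 * m), b2 = numeric(m))
  rnd_blk <- list(W1 = matrix(stats::rnorm(m * 3 * m, sd = 0.2), m),
                  b1 = stats::rnorm(m),
                  W2 = matrix(stats::rnorm(m * 3 * m, sd = 0.2), m),
                  b2 = stats::rnorm(m))
  for (n in c(1L, 3L, 8L)) {
    rep <- matrix(stats::rnorm(m * n), m, n)
    expect_identical(conv_block(rep, zero_blk), rep)
    expect_identical(dim(conv_block(rep, rnd_blk)), dim(rep))
  }
  # hand z + f(z) at m = 1, length 3
  blk <- list(W1 = matrix(c(1, 2, 3), 1, 3), b1 = 0.1,
              W2 = matrix(c(-1, 1, 2), 1, 3), b2 = 0)
  z <- matrix(c(1, -1, 2), 1, 3)
  a1 <- pmax(z, 0)
  u1 <- c(2 * a1[1] + 3 * a1[2] + 0.1,
          1 * a1[1] + 2 * a1[2] + 3 * a1[3] + 0.1,
          1 * a1[2] + 2 * a1[3] + 0.1)
  a2 <- pmax(u1, 0)
  u2 <- c(1 * a2[1] + 2 * a2[2],
          -1 * a2[1] + 1 * a2[2] + 2 * a2[3],
          -1 * a2[2] + 1 * a2[3])
  expect_equal(drop(conv_block(z, blk)), drop(z) + u2, tolerance = 1e-12)
})

test_that("downsampling halves the length with -Inf padded max windows", {
  expect_identical(ncol(downsample(matrix(0, 2, 8))), 4L)
  expect_identical(ncol(downsample(matrix(0, 2, 1))), 1L)
  expect_identical(drop(downsample(matrix(c(1, 5, 2, 4, 3), 1, 5))),
                   c(5, 5, 4))
  for (n in c(2L, 7L, 13L)) {
    expect_identical(ncol(downsample(matrix(stats::rnorm(3 * n), 3, n))),
                     as.integer(ceiling(n / 2)))
  }
})

test_that("global max pool is the componentwise max, permutation-invariant", {
  rep <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_identical(final_pool(rep), c(1, 2))
  expect_identical(final_pool(matrix(c(3, 7), 2, 1)), c(3, 7))
  set.seed(34)
  rep <- matrix(stats::rnorm(12), 3, 4)
  expect_identical(final_pool(rep), final_pool(rep[, c(3, 1, 4, 2)]))
})

test_that("forward pass yields normalized probabilities", {
  uv <- build_unit_vocab("abc")
  cfg <- endcnn_config(k = 3, m = 4, depth = 7, keep_prob = 1)
  model <- endcnn_init(cfg, uv, seed = 5)
  units <- vocab_lookup(c("a", "b", "c", "a", "b"), uv)
  p <- endcnn_forward(units, model)
  expect_length(p, 2L)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(endcnn_forward(integer(0), model), "empty")
  # all-zero weights -> (0.5, 0.5): symmetric head
  m0 <- endcnn_init(cfg, uv, seed = 5, zero_blocks = TRUE)
  m0$params$region_W[] <- 0
  m0$params$head_W[] <- 0
  expect_equal(endcnn_forward(units, m0), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("zero blocks leave the output unchanged at any depth", {
  uv <- build_unit_vocab("abcdef")
  units <- vocab_lookup(strsplit("abcfedcbafed", "")[[1]], uv)
  ref <- NULL
  for (depth in c(3L, 7L, 15L)) {  # 1, 3, 7 blocks
    cfg <- endcnn_config(k = 3, m = 6, depth = depth, keep_prob = 1)
    model <- endcnn_init(cfg, uv, seed = 8, zero_blocks = TRUE)
    p <- endcnn_forward(units, model)
    if (is.null(ref)) ref <- p else expect_equal(p, ref, tolerance = 1e-12)
  }
})

test_that("every shortcut addition is shape-equal by construction", {
  # structural check: blocks preserve shape for any k and depth, so the
  # shortcut operands always match
  uv <- build_unit_vocab("ab")
  for (k in c(1L, 7L, 14L)) {
    for (blocks in c(1L, 5L, 12L)) {
      cfg <- endcnn_config(k = k, m = 3, depth = 1L + 2L * blocks,
                           keep_prob = 1)
      model <- endcnn_init(cfg, uv, seed = 2)
      units <- rep(vocab_lookup(c("a", "b"), uv), 10)
      rep_ <- region_embed(units, model$params$region_W,
                           model$params$region_b, cfg$k,
                           length(uv$tokens))
      for (b in seq_len(cfg$n_blocks)) {
        out <- conv_block(rep_, model$params$blocks[[b]])
        expect_identical(dim(out), dim(rep_))
        if (b < cfg$n_blocks && ncol(out) >= 3L) out <- downsample(out)
        rep_ <- out
      }
      expect_silent(endcnn_forward(units, model))
    }
  }
})

test_that("MAC accounting follows the halving geometry", {
  cfg <- endcnn_config()  # 7 blocks, m = 250, ks = 3
  macs <- count_macs(cfg, 64)
  expect_length(macs, 7L)
  expect_equal(macs[1], 64 * 2 * 3 * 250^2)
  # consecutive ratio exactly 1/2 at power-of-two lengths
  for (len in c(64, 256, 1024)) {
    macs <- count_macs(cfg, len)
    expect_equal(macs[-1] / macs[-length(macs)],
                 rep(0.5, length(macs) - 1))
  }
  # one-block network: total equals first
  cfg1 <- endcnn_config(depth = 3)
  expect_equal(sum(count_macs(cfg1, 100)) / count_macs(cfg1, 100)[1], 1)
  # ceiling-corrected bound for arbitrary lengths and depths:
  # sum <= 2 x first + (blocks - 1) extra positions
  for (blocks in c(2L, 7L, 12L)) {
    cfgb <- endcnn_config(depth = 1L + 2L * blocks)
    per_pos <- 2 * 3 * 250^2
    for (len in c(64, 65, 100, 383, 5000, 10000)) {
      macs <- count_macs(cfgb, len)
      expect_lte(sum(macs), 2 * macs[1] + (blocks - 1) * per_pos)
    }
  }
})

test_that("receptive field grows like 2^L with jump 2^L", {
  cfg <- endcnn_config()  # k = 7, ks = 3
  rf0 <- receptive_field(cfg, 0)
  expect_equal(rf0$r, 11)  # k + 2*(ks-1) with one block
  expect_equal(rf0$jump, 1)
  for (L in 0:10) {
    expect_equal(receptive_field(cfg, L)$jump, 2^L)
  }
  ratios <- vapply(3:9, function(L) {
    receptive_field(cfg, L + 1)$r / receptive_field(cfg, L)$r
  }, numeric(1))
  expect_true(all(ratios >= 1.8 & ratios <= 2.0))
})

test_that("classifier training descends, memorizes, and is deterministic", {
  set.seed(36)
  uv <- build_unit_vocab("abcdef")
  sch <- tag_scheme()
  mk_doc <- function(pos) {
    # positive docs contain the HyC label token, negatives DiA
    code <- if (pos) "HyC" else "DiA"
    ms <- list(risk_factor_mention("Hy", "C", 0L, 3L, "abc"),
               risk_factor_mention("Di", "A", 4L, 7L, "def"))
    keep <- if (pos) ms[1] else ms[2]
    list(units = mentions_to_units(keep, uv), label = as.integer(pos))
  }
  ds <- c(lapply(rep(TRUE, 5), mk_doc), lapply(rep(FALSE, 5), mk_doc))
  cfg <- endcnn_config(k = 3, m = 8, depth = 5, epochs = 120, batch = 4)
  mod <- train_classifier(ds, uv, cfg, seed = 6)
  expect_lt(mod$loss_history[length(mod$loss_history)],
            mod$loss_history[1])
  pred <- vapply(ds, function(d) {
    as.integer(endcnn_forward(d$units, mod)[2] > 0.5)
  }, integer(1))
  gold <- vapply(ds, `[[`, numeric(1), "label")
  expect_equal(classification_metrics(gold, pred)$accuracy, 1)
  mod2 <- train_classifier(ds, uv, cfg, seed = 6)
  expect_identical(mod$loss_history, mod2$loss_history)
  expect_warning(train_classifier(ds[1:5], uv, cfg, seed = 1),
                 "single class")
})

test_that("learning-rate schedule matches lr * dr^(g/ds)", {
  expect_equal(lr_schedule(0.001, 0.99, 500, 0), 0.001)
  expect_equal(lr_schedule(0.001, 0.99, 500, 500), 0.001 * 0.99)
  expect_equal(lr_schedule(0.001, 0.99, 500, 1250), 0.001 * 0.99^2.5)
})
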