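test_that("LSTM cell matches a by-hand single-step evaluation", {
  p <- emrisk:::lstm_init(2, 1, init_scale = 0)
  p$W <- matrix(c(0.5, 0.3, 0.1,
                  -0.2, 0.4, 0.6,
                  0.3, -0.1, 0.2,
                  0.7, 0.2, -0.3), nrow = 4, byrow = TRUE)
  p$b <- c(0.1, -0.1, 0.2, 0.05)
  x <- matrix(c(0.4, -0.7), 1, 2)
  sig <- function(z) 1 / (1 + exp(-z))
  xh <- c(0.4, -0.7, 0)
  i <- sig(sum(p$W[1, ] * xh) + 0.1)
  g <- tanh(sum(p$W[4, ] * xh) + 0.05)
  o <- sig(sum(p$W[3, ] * xh) + 0.2)
  expect_equal(emrisk:::lstm_forward(x, p)$h[1, 1], o * tanh(i * g),
               tolerance = 1e-12)
})

test_that("all-zero parameters are a fixed point of the recurrence", {
  p <- emrisk:::lstm_init(3, 4, init_scale = 0)
  p$b[] <- 0
  h <- emrisk:::lstm_forward(matrix(stats::rnorm(15), 5, 3), p)$h
  expect_true(all(h == 0))
})

test_that("bilstm output has shape n x 2H and direction symmetry", {
  set.seed(21)
  params <- list(fwd = emrisk:::lstm_init(3, 5), bwd = emrisk:::lstm_init(3, 5))
  for (n in sample(1:20, 4)) {
    x <- matrix(stats::rnorm(3 * n), n, 3)
    h <- bilstm_encode(x, params)
    expect_identical(dim(h), c(n, 10L))
  }
  # reversing input and swapping directions swaps the halves
  x <- matrix(stats::rnorm(18), 6, 3)
  h1 <- bilstm_encode(x, params)
  h2 <- bilstm_encode(x[6:1, , drop = FALSE],
                      list(fwd = params$bwd, bwd = params$fwd))
  expect_equal(h1, h2[6:1, c(6:10, 1:5)], tolerance = 1e-12)
  # empty input
  expect_identical(dim(bilstm_encode(matrix(0, 0, 3), params)), c(0L, 10L))
})

test_that("emission layer is the rowwise tanh projection, range (-1,1)", {
  set.seed(22)
  h <- matrix(stats::rnorm(12), 3, 4)
  w <- matrix(stats::rnorm(8), 2, 4)
  p <- emission_scores(h, w)
  expect_equal(p[2, 1], tanh(sum(w[1, ] * h[2, ])), tolerance = 1e-12)
  expect_true(all(abs(p) < 1))
  expect_true(all(emission_scores(h, w * 0) == 0))
  expect_error(emission_scores(h, matrix(0, 2, 5)), "dimensional")
})

test_that("BIO decoding: spans, repair rule, and round trip", {
  sch <- tag_scheme()
  m <- decode_mentions(c("X", "Y", "Z", "a"),
                       c("B-HyC", "I-HyC", "I-HyC", "O"), sch)
  expect_length(m, 1L)
  expect_identical(m[[1]]$type, "Hy")
  expect_identical(m[[1]]$temporal, "C")
  expect_identical(c(m[[1]]$start, m[[1]]$end), c(0L, 3L))
  expect_identical(m[[1]]$surface, "XYZ")

  expect_identical(decode_mentions("ab", c("O", "O"), sch), list())

  # orphan I- repaired to B-
  m <- decode_mentions(c("X", "a"), c("I-HyD", "O"), sch)
  expect_length(m, 1L)
  expect_identical(c(m[[1]]$start, m[[1]]$end), c(0L, 1L))
  expect_identical(m[[1]]$temporal, "D")
  # I- with a different code starts a new mention
  m <- decode_mentions(c("X", "Y"), c("B-HyC", "I-DiC"), sch)
  expect_length(m, 2L)

  # round trip: tags of gold mentions decode to the gold mentions
  corp <- small_synth(25)
  for (i in seq_along(corp$train$sentences)) {
    s <- corp$train$sentences[[i]]
    dec <- decode_mentions(s$chars, s$tags, sch)
    gold <- corp$train$mentions[[i]]
    expect_length(dec, length(gold))
    for (j in seq_along(gold)) {
      expect_identical(dec[[j]][c("type", "temporal", "start", "end")],
                       gold[[j]][c("type", "temporal", "start", "end")])
    }
  }
})

test_that("training memorizes a toy corpus and is seed-deterministic", {
  corp <- toy_corpus()
  cfg <- labeler_config(d_w = 12, hidden = 12, epochs = 150)
  mod <- train_labeler(corp, config = cfg, seed = 4)
  # loss decreases
  expect_lt(mod$loss_history[length(mod$loss_history)],
            mod$loss_history[1])
  # memorization: every training sentence decoded exactly
  pred <- lapply(corp, function(s) {
    decode_mentions(s$chars, predict_tags(mod, s$chars))
  })
  gold <- lapply(corp, function(s) decode_mentions(s$chars, s$tags))
  prf <- entity_prf(gold, pred)
  expect_equal(prf$fscore, 1)
  # determinism
  mod2 <- train_labeler(corp, config = cfg, seed = 4)
  expect_identical(predict_tags(mod, corp[[1]]$chars),
                   predict_tags(mod2, corp[[1]]$chars))
  expect_identical(mod$loss_history, mod2$loss_history)
})

test_that("training rejects malformed inputs before starting", {
  expect_error(train_labeler(list()), "empty")
  bad <- list(structure(list(chars = c("a"), tags = c("B-XXX")),
                        class = "annotated_sentence"))
  expect_error(train_labeler(bad), "unknown tag")
})
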