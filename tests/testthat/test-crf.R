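test_that("path score matches its closed form on degenerate cases", {
  set.seed(11)
  # zero scores -> zero for every path
  P <- matrix(0, 3, 2)
  T0 <- matrix(0, 3, 2)
  for (y in list(c(1L, 1L, 1L), c(2L, 1L, 2L))) {
    expect_identical(crf_path_score(P, T0, y), 0)
  }
  # n = 1: start transition plus emission
  inst <- random_crf_instance(1, 4)
  for (j in 1:4) {
    expect_equal(crf_path_score(inst$P, inst$T, j),
                 inst$T[1, j] + inst$P[1, j])
  }
  # n = 3 random instance vs explicit sum
  inst <- random_crf_instance(3, 2)
  y <- c(2L, 1L, 2L)
  expect_equal(crf_path_score(inst$P, inst$T, y),
               inst$T[1, 2] + inst$P[1, 2] + inst$T[3, 1] + inst$P[2, 1] +
                 inst$T[2, 2] + inst$P[3, 2])
  expect_error(crf_path_score(inst$P, inst$T, c(1L, 5L, 1L)), "range")
})

test_that("log-partition equals enumeration and dominates every path", {
  set.seed(12)
  # uniform case: n=1, m tags, all scores zero -> log m
  for (m in c(1L, 3L, 7L)) {
    expect_equal(crf_log_partition(matrix(0, 1, m), matrix(0, m + 1, m)),
                 log(m))
  }
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    m <- sample(1:4, 1)
    inst <- random_crf_instance(n, m)
    sc <- brute_scores(inst$P, inst$T)
    lz <- crf_log_partition(inst$P, inst$T)
    expect_equal(lz, log(sum(exp(sc))), tolerance = 1e-10)
    expect_true(all(lz >= sc))
  }
  # numerical stability at large magnitudes
  inst <- random_crf_instance(6, 5, lim = 1000)
  expect_true(is.finite(crf_log_partition(inst$P, inst$T)))
  expect_error(crf_log_partition(matrix(numeric(), 0, 3), matrix(0, 4, 3)),
               "n >= 1")
})

test_that("log-likelihood normalizes to a probability distribution", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(1:4, 1)
    m <- sample(1:3, 1)
    inst <- random_crf_instance(n, m)
    paths <- enumerate_paths(n, m)
    ll <- apply(paths, 1, function(y) {
      crf_log_likelihood(inst$P, inst$T, as.integer(y))
    })
    expect_true(all(ll <= 1e-12))
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-8)
  }
  # single-tag degenerate case: only one path, probability 1
  inst <- random_crf_instance(3, 1)
  expect_equal(crf_log_likelihood(inst$P, inst$T, c(1L, 1L, 1L)), 0,
               tolerance = 1e-12)
})

test_that("Viterbi agrees with brute force and breaks ties low", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    m <- sample(1:5, 1)
    inst <- random_crf_instance(n, m)
    sc <- brute_scores(inst$P, inst$T)
    vit <- crf_viterbi(inst$P, inst$T)
    expect_equal(vit$score, max(sc), tolerance = 1e-10)
    expect_equal(crf_path_score(inst$P, inst$T, vit$path), vit$score,
                 tolerance = 1e-10)
  }
  # zero transitions -> per-position argmax of emissions
  P <- matrix(c(0.3, 0.9, 0.1, 0.2, 0.8, 0.7), 3, 2)
  vit <- crf_viterbi(P, matrix(0, 3, 2))
  expect_identical(vit$path,
                   as.integer(apply(P, 1, which.max)))
  # all-equal scores -> all-lowest-index path (documented tie rule)
  vit <- crf_viterbi(matrix(1, 4, 3), matrix(1, 4, 3))
  expect_identical(vit$path, rep(1L, 4))
})

test_that("CRF gradients match finite differences", {
  set.seed(15)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    m <- sample(2:4, 1)
    inst <- random_crf_instance(n, m)
    y <- sample(seq_len(m), n, replace = TRUE)
    g <- emrisk:::crf_loss_grad(inst$P, inst$T, y)
    expect_equal(g$loss, -crf_log_likelihood(inst$P, inst$T, y),
                 tolerance = 1e-10)
    eps <- 1e-6
    for (k in 1:4) {
      i <- sample(n, 1)
      j <- sample(m, 1)
      P2 <- inst$P
      P2[i, j] <- P2[i, j] + eps
      fd <- (-crf_log_likelihood(P2, inst$T, y) +
               crf_log_likelihood(inst$P, inst$T, y)) / eps
      expect_equal(fd, g$d_emissions[i, j], tolerance = 1e-4)
      a <- sample(m + 1, 1)
      T2 <- inst$T
      T2[a, j] <- T2[a, j] + eps
      fd <- (-crf_log_likelihood(inst$P, T2, y) +
               crf_log_likelihood(inst$P, inst$T, y)) / eps
      expect_equal(fd, g$d_trans[a, j], tolerance = 1e-4)
    }
  }
})
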