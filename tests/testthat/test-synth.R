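test_that("planted rule counts distinct active types against theta", {
  mk <- function(type, temporal) {
    risk_factor_mention(type, temporal, 0L, 1L, "x")
  }
  expect_identical(planted_rule(list()), 0L)
  # 3 distinct types, all Continue, theta = 3 -> positive
  m3 <- list(mk("Hy", "C"), mk("Di", "C"), mk("Sm", "C"))
  expect_identical(planted_rule(m3, theta = 3), 1L)
  # 5 mentions of only 2 distinct types -> negative (distinctness counts)
  m5 <- list(mk("Hy", "C"), mk("Hy", "C"), mk("Hy", "D"),
             mk("Di", "C"), mk("Di", "D"))
  expect_identical(planted_rule(m5, theta = 3), 0L)
  # inactive temporal attributes do not count
  mb <- list(mk("Hy", "B"), mk("Di", "A"), mk("Sm", "B"))
  expect_identical(planted_rule(mb, theta = 3), 0L)
  expect_identical(planted_rule(mb, theta = 3, active_set = c("A", "B")),
                   1L)
})

test_that("generated documents are BIO-valid with consistent labels", {
  set.seed(13)
  cfg <- synth_config(n_docs = 10)
  sch <- tag_scheme()
  for (i in 1:25) {
    d <- generate_document(cfg, scheme = sch)
    s <- d$sentence
    validate_tags(s$tags, sch)
    # no orphan I- anywhere
    prev <- "O"
    for (t in seq_along(s$tags)) {
      tg <- s$tags[[t]]
      if (startsWith(tg, "I-")) {
        expect_identical(substring(prev, 3), substring(tg, 3))
      }
      prev <- tg
    }
    # decoding the gold tags recovers the planted mentions
    dec <- decode_mentions(s$chars, s$tags, sch)
    expect_length(dec, length(d$mentions))
    for (j in seq_along(dec)) {
      expect_identical(
        dec[[j]][c("type", "temporal", "start", "end", "surface")],
        d$mentions[[j]][c("type", "temporal", "start", "end", "surface")])
    }
    # label consistency with the planted rule
    expect_identical(d$document$label,
                     planted_rule(d$mentions, cfg$theta, cfg$active_set))
    # Age/Gender always temporal None
    for (m in d$mentions) {
      if (m$type %in% c("Age", "Gen")) expect_identical(m$temporal, "N")
    }
  }
})

test_that("document generation honors a forced target label", {
  set.seed(14)
  cfg <- synth_config(n_docs = 10)
  for (i in 1:10) {
    expect_identical(generate_document(cfg, target_label = 1L)$document$label,
                     1L)
    expect_identical(generate_document(cfg, target_label = 0L)$document$label,
                     0L)
  }
})

test_that("corpus generation is reproducible with reference-ratio splits", {
  cfg <- synth_config(n_docs = 659, seed = 13)
  # split ratios at the reference corpus size
  c1 <- generate_corpus(synth_config(n_docs = 40, seed = 13))
  expect_identical(vapply(c1[c("train", "dev", "test")],
                          function(s) length(s$documents), integer(1)),
                   c(train = 28L, dev = 4L, test = 8L))
  n <- 659
  expect_identical(round(n * 461 / 659), 461)
  expect_identical(round(n * 66 / 659), 66)

  # determinism: same seed, same corpus (text and labels)
  c2 <- generate_corpus(synth_config(n_docs = 40, seed = 13))
  expect_identical(vapply(c1$train$documents, `[[`, character(1), "text"),
                   vapply(c2$train$documents, `[[`, character(1), "text"))
  expect_identical(vapply(c1$train$documents, `[[`, integer(1), "label"),
                   vapply(c2$train$documents, `[[`, integer(1), "label"))
  expect_error(generate_corpus(synth_config(n_docs = 5)), "at least 10")
})

test_that("realized prevalence concentrates on the target", {
  corp <- generate_corpus(synth_config(n_docs = 500, prevalence = 0.8,
                                       seed = 13))
  labels <- vapply(c(corp$train$documents, corp$dev$documents,
                     corp$test$documents), `[[`, integer(1), "label")
  expect_gte(mean(labels), 0.75)
  expect_lte(mean(labels), 0.85)
})

test_that("infeasible configurations fail loudly", {
  cfg <- synth_config(n_docs = 10, lambda_mentions = 0.01)
  set.seed(15)
  # demanding a positive label with essentially no mentions must error
  expect_error(generate_document(cfg, target_label = 1L, max_tries = 50L),
               "rejection")
  expect_error(synth_config(lexicon = list(Hy = character())), "empty")
})
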